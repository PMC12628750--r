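# Per-read repeat-content profiling: maximal exact tandem runs of target
# motifs and the derived per-motif / total repeat bp quantities that the
# mixed-motif pair screen thresholds.

#' Find maximal exact tandem runs of target motifs in a read
#'
#' A run is a maximal substring that matches cyclic repetitions of some
#' rotation of a target motif (or of its reverse complement when
#' `both_strands = TRUE`).  Detection uses the periodicity identity
#' `seq[i] == seq[i + k]` for motif length `k`: every maximal period-`k`
#' stretch whose leading k-mer belongs to a target motif's equivalence class
#' is a run.  `N` bases never match and therefore break runs.
#'
#' @param seq DNA string (uppercase; `N` allowed).
#' @param motifs target motifs (see [as_motif_list()]), pairwise distinct by
#'   canonical key.
#' @param min_run_bp minimum run length in bp; default two full copies of each
#'   motif (so 10 bp for pentamers, 30 bp for a 15-mer).  A single value
#'   applies to all motifs but is floored at `motif length + 1`.
#' @param both_strands match rotations of the reverse complement too.
#' @return data.frame with columns `start` (0-based), `end` (exclusive),
#'   `motif` (display string), `canonical`, `bp`, `copies` (`bp / length`),
#'   sorted by `start` then motif order in the input list.
#' @examples
#' find_runs(strrep("TTGTA", 30), "TTGTA")
#' @export
find_runs <- function(seq, motifs, min_run_bp = NULL, both_strands = TRUE) {
  motifs <- as_motif_list(motifs)
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  n <- nchar(seq)
  empty <- data.frame(start = integer(0), end = integer(0),
                      motif = character(0), canonical = character(0),
                      bp = integer(0), copies = numeric(0))
  if (n == 0L) return(empty)

  r <- charToRaw(seq)
  valid <- r %in% charToRaw("ACGT")
  keyfun <- if (both_strands) canonical_key else rotation_key
  mkeys <- vapply(motifs, function(m)      # classification keys
    if (both_strands) m$canonical_key else rotation_key(m$display), character(1))
  ckeys <- vapply(motifs, `[[`, character(1), "canonical_key")  # reported
  mlens <- vapply(motifs, `[[`, integer(1), "length")

  badcs <- c(0L, cumsum(!valid))  # prefix counts of non-ACGT bases
  out <- vector("list", length(unique(mlens)))
  for (ki in seq_along(unique(mlens))) {
    k <- unique(mlens)[ki]
    if (n < k + 1L) next
    ok <- (r[seq_len(n - k)] == r[(k + 1L):n]) &
      valid[seq_len(n - k)] & valid[(k + 1L):n]
    rl <- rle(ok)
    ends <- cumsum(rl$lengths)
    a <- (ends - rl$lengths + 1L)[rl$values]  # stretch starts == seq pos
    b <- ends[rl$values]
    if (length(a) == 0L) next
    L <- b - a + 1L + k
    # the leading k-mer (which defines the run's motif class) must be clean
    kmer_ok <- (badcs[a + k] - badcs[a]) == 0L
    a <- a[kmer_ok]; b <- b[kmer_ok]; L <- L[kmer_ok]
    if (length(a) == 0L) next
    kmer <- substring(seq, a, a + k - 1L)
    ukm <- unique(kmer)
    ukey <- vapply(ukm, keyfun, character(1))
    key <- ukey[match(kmer, ukm)]
    mi <- match(key, mkeys)                   # motif index or NA
    minbp <- pmax(if (is.null(min_run_bp)) 2L * mlens else
                    rep(as.integer(min_run_bp), length(mlens)),
                  mlens + 1L)
    keep <- !is.na(mi) & L >= minbp[ifelse(is.na(mi), 1L, mi)]
    if (!any(keep)) next
    out[[ki]] <- data.frame(
      start = a[keep] - 1L, end = b[keep] + k,
      motif = vapply(motifs[mi[keep]], `[[`, character(1), "display"),
      canonical = ckeys[mi[keep]], bp = L[keep], copies = L[keep] / k)
  }
  runs <- do.call(rbind, c(list(empty), out[!vapply(out, is.null, logical(1))]))
  morder <- match(runs$canonical, ckeys)
  runs <- runs[order(runs$start, morder), , drop = FALSE]
  rownames(runs) <- NULL
  runs
}

# union width of a set of [start, end) intervals
.union_bp <- function(start, end) {
  if (length(start) == 0L) return(0L)
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(start + 1L, end))))
}

#' Profile the repeat content of a read
#'
#' Computes, per target motif, the union base-pair coverage of that motif's
#' maximal tandem runs, and the total repeat bp as the union over all runs of
#' all motifs (overlapping runs of different motifs are not double counted).
#' These are the read-level quantities thresholded by the mixed-motif pair
#' screen (`> 125` bp total repeat per read by default).
#'
#' @inheritParams find_runs
#' @param read_id read identifier carried into the profile.
#' @return object of class `read_repeat_profile`: list with `read_id`,
#'   `read_length`, `per_motif_bp` (named by canonical key), `display`
#'   (canonical key -> display name), `total_repeat_bp`, `runs`.
#' @export
profile_read <- function(read_id, seq, motifs, min_run_bp = NULL,
                         both_strands = TRUE) {
  motifs <- as_motif_list(motifs)
  runs <- find_runs(seq, motifs, min_run_bp = min_run_bp,
                    both_strands = both_strands)
  keys <- vapply(motifs, `[[`, character(1), "canonical_key")
  per <- vapply(keys, function(k) {
    i <- runs$canonical == k
    .union_bp(runs$start[i], runs$end[i])
  }, integer(1))
  names(per) <- keys
  structure(list(
    read_id = read_id,
    read_length = nchar(seq),
    per_motif_bp = per,
    display = stats::setNames(vapply(motifs, `[[`, character(1), "display"), keys),
    total_repeat_bp = .union_bp(runs$start, runs$end),
    runs = runs), class = "read_repeat_profile")
}

#' @export
print.read_repeat_profile <- function(x, ...) {
  cat(sprintf("<read_repeat_profile> %s (%d bp, %d bp repeat)\n",
              x$read_id, x$read_length, x$total_repeat_bp))
  for (k in names(x$per_motif_bp))
    cat(sprintf("  %s: %d bp\n", x$display[[k]], x$per_motif_bp[[k]]))
  invisible(x)
}

# build a profile directly from known per-motif bp (used by tests and the
# boundary-case generators; bypasses sequence scanning)
profile_from_bp <- function(read_id, read_length, per_motif_bp, display = NULL,
                            total_repeat_bp = NULL) {
  keys <- vapply(names(per_motif_bp), canonical_key, character(1))
  per <- stats::setNames(as.integer(per_motif_bp), keys)
  if (is.null(display)) display <- stats::setNames(names(per_motif_bp), keys)
  if (is.null(total_repeat_bp))
    total_repeat_bp <- min(read_length, sum(per))
  structure(list(read_id = read_id, read_length = as.integer(read_length),
                 per_motif_bp = per, display = display,
                 total_repeat_bp = as.integer(total_repeat_bp),
                 runs = NULL), class = "read_repeat_profile")
}

#' Profile many reads at once
#'
#' @inheritParams profile_read
#' @param ids,seqs parallel vectors of read ids and sequences.
#' @return list of `read_repeat_profile`.
#' @export
profile_reads <- function(ids, seqs, motifs, min_run_bp = NULL,
                          both_strands = TRUE) {
  stopifnot(length(ids) == length(seqs))
  motifs <- as_motif_list(motifs)
  Map(function(id, s) profile_read(id, s, motifs, min_run_bp, both_strands),
      ids, as.character(seqs))
}

#' Per-read tabular repeat profile
#'
#' Flattens profiles into the per-read TSV layout: read id, length, one bp
#' column per motif (named by display string), and total repeat bp.
#'
#' @param profiles list of `read_repeat_profile`.
#' @return data.frame.
#' @export
profile_table <- function(profiles) {
  stopifnot(length(profiles) > 0L)
  disp <- profiles[[1]]$display
  tab <- data.frame(read_id = vapply(profiles, `[[`, character(1), "read_id"),
                    read_length = vapply(profiles, `[[`, integer(1), "read_length"))
  for (k in names(disp))
    tab[[paste0(disp[[k]], "_bp")]] <-
      vapply(profiles, function(p) p$per_motif_bp[[k]], integer(1))
  tab$total_repeat_bp <- vapply(profiles, `[[`, integer(1), "total_repeat_bp")
  tab
}

#' Fraction of a read covered by one motif's repeat runs
#'
#' The read-level purity measure behind the "paired in-repeat read" style
#' criterion (`> 90%` of the read in target-motif repeat).
#'
#' @param profile a `read_repeat_profile`.
#' @param motif motif string or `repeat_motif`.
#' @return numeric in `[0, 1]`; `0` with a warning when the motif was not in
#'   the profiled motif set.
#' @export
repeat_fraction <- function(profile, motif) {
  stopifnot(inherits(profile, "read_repeat_profile"))
  key <- if (inherits(motif, "repeat_motif")) motif$canonical_key else
    canonical_key(motif)
  if (!key %in% names(profile$per_motif_bp)) {
    warning("motif ", if (is.character(motif)) motif else motif$display,
            " not in profiled motif set; returning 0", call. = FALSE)
    return(0)
  }
  unname(profile$per_motif_bp[[key]] / profile$read_length)
}
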