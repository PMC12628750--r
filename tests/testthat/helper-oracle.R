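# Independent brute-force oracle for maximal tandem-run detection.
#
# Method (deliberately different from the package's periodicity scan): for
# every phase-anchored periodic template of every rotation of the motif (and
# of its reverse complement), mark per-position template agreement, take
# maximal TRUE stretches, drop sub-minimum stretches, and de-duplicate
# stretches contained in longer ones of the same motif.  This enumerates
# every (start, end, rotation) combination implicitly but exhaustively.

oracle_find_runs <- function(seq, motifs, min_run_bp = NULL,
                             both_strands = TRUE) {
  motifs <- pentaplex::as_motif_list(motifs)
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  out <- list()
  for (m in motifs) {
    k <- m$length
    minbp <- max(if (is.null(min_run_bp)) 2L * k else min_run_bp, k + 1L)
    tmpls <- pentaplex::rotations(m$display)
    if (both_strands)
      tmpls <- unique(c(tmpls, pentaplex::rotations(pentaplex::revcomp(m$display))))
    cand <- list()
    for (t in tmpls) {
      tv <- rep(strsplit(t, "")[[1]], length.out = n)
      rl <- rle(ch == tv)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      hit <- which(rl$values & rl$lengths >= minbp)
      for (j in hit)
        cand[[length(cand) + 1L]] <- c(starts[j] - 1L, ends[j])
    }
    if (length(cand) == 0L) next
    cand <- unique(do.call(rbind, cand))
    # maximality: drop stretches contained in another stretch of this motif
    keep <- vapply(seq_len(nrow(cand)), function(i) {
      !any(cand[-i, 1] <= cand[i, 1] & cand[-i, 2] >= cand[i, 2])
    }, logical(1))
    cand <- cand[keep, , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      start = cand[, 1], end = cand[, 2], motif = m$display,
      canonical = m$canonical_key, bp = cand[, 2] - cand[, 1],
      copies = (cand[, 2] - cand[, 1]) / k)
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), canonical = character(0),
                      bp = integer(0), copies = numeric(0)))
  runs <- do.call(rbind, out)
  runs <- runs[order(runs$start, runs$motif), , drop = FALSE]
  rownames(runs) <- NULL
  runs
}

# canonical comparison form: sorted (start, end, canonical) triples
run_set <- function(runs) {
  x <- runs[order(runs$start, runs$end, runs$canonical),
            c("start", "end", "canonical")]
  rownames(x) <- NULL
  x
}

# random read with no structure (uniform ACGT)
random_read <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                 collapse = "")

# random read with planted repeat tracts to exercise run detection
planted_read <- function(n, motifs) {
  s <- strsplit(random_read(n), "")[[1]]
  for (i in seq_len(sample(0:3, 1))) {
    m <- sample(motifs, 1)
    cp <- sample(2:10, 1)
    tract <- strsplit(strrep(m, cp), "")[[1]]
    if (runif(1) < 0.5)
      tract <- rev(chartr("ACGT", "TGCA", tract))
    pos <- sample(seq_len(max(1L, n - length(tract))), 1)
    s[pos:(pos + length(tract) - 1L)] <- tract
  }
  paste(s[seq_len(n)], collapse = "")
}

fame_motifs <- c("TTTTA", "TTTCA", "TTGTA", "TTCCA")
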