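# Long-read characterization of a repeat locus: region extraction, motif
# counting, wild-type and basecall-artifact filtering, segmentation of each
# read into ordered motif blocks, consensus structures and waterfall
# summaries.

#' Extract reads overlapping a target region from an alignment-derived table
#'
#' Keeps whole reads (no clipping): large expansions are absent from the
#' reference, so alignments anchor in the flanks and the repeat itself lies
#' outside the aligned interval.  Reverse-strand reads are
#' reverse-complemented so all returned records share the reference-forward
#' orientation; the original strand is retained for the basecall-artifact
#' filter.
#'
#' @param read_table data.frame with columns `read_id`, `contig`, `start`,
#'   `end` (0-based half-open aligned interval), `strand` (`"forward"`,
#'   `"reverse"` or `"unknown"`, `+`/`-` accepted) and `seq` (the read as
#'   sequenced).
#' @param region region string (see [parse_region()]) or parsed list.
#' @return data.frame (`read_id`, `seq`, `strand`, `overlaps_region`) with
#'   sequences oriented reference-forward; empty with a warning when the
#'   region contig is absent from the table.
#' @export
extract_region_reads <- function(read_table, region) {
  stopifnot(all(c("read_id", "contig", "start", "end", "strand", "seq")
                %in% names(read_table)))
  if (is.character(region)) region <- parse_region(region)
  strand <- c("+" = "forward", "-" = "reverse")[read_table$strand]
  strand[is.na(strand)] <- read_table$strand[is.na(strand)]
  if (!all(strand %in% c("forward", "reverse", "unknown")))
    stop("strand must be forward/reverse/unknown (or +/-)", call. = FALSE)
  if (!any(read_table$contig == region$contig)) {
    warning("region contig ", region$contig, " absent from read table",
            call. = FALSE)
    return(data.frame(read_id = character(0), seq = character(0),
                      strand = character(0), overlaps_region = logical(0)))
  }
  hit <- read_table$contig == region$contig &
    read_table$start < region$end & read_table$end > region$start
  out <- data.frame(read_id = read_table$read_id[hit],
                    seq = read_table$seq[hit],
                    strand = strand[hit],
                    overlaps_region = TRUE)
  rev <- out$strand == "reverse"
  if (any(rev)) out$seq[rev] <- revcomp(out$seq[rev])
  message(nrow(out), " read(s) overlap region ",
          sprintf("%s:%d-%d", region$contig, region$start + 1L, region$end))
  out
}

#' Count tandem motif copies per read
#'
#' Copies are tandem-run copies: per-motif union run bp divided by the motif
#' length (so interrupted occurrences count only within runs of at least two
#' copies).  `total_repeat_bp` is the union over all motifs' runs.
#'
#' @param records data.frame with `read_id` and `seq` (e.g. from
#'   [extract_region_reads()]), or a single sequence string.
#' @param motifs target motifs.
#' @param both_strands match reverse-complement rotations too.
#' @return data.frame: `read_id`, one `<MOTIF>_copies` column per motif, and
#'   `total_repeat_bp`.
#' @examples
#' count_motifs("TACGCATCCCAGTTTGAGACGTTGTATTGTATTGTATTGTATTGTATTGTA", "TTGTA")
#' @export
count_motifs <- function(records, motifs, both_strands = TRUE) {
  motifs <- as_motif_list(motifs)
  if (is.character(records))
    records <- data.frame(read_id = sprintf("read%d", seq_along(records)),
                          seq = records)
  profs <- profile_reads(records$read_id, records$seq, motifs,
                         both_strands = both_strands)
  keys <- vapply(motifs, `[[`, character(1), "canonical_key")
  out <- data.frame(read_id = records$read_id)
  for (i in seq_along(motifs))
    out[[paste0(motifs[[i]]$display, "_copies")]] <-
      vapply(profs, function(p) p$per_motif_bp[[keys[i]]], integer(1)) /
      motifs[[i]]$length
  out$total_repeat_bp <- vapply(profs, `[[`, integer(1), "total_repeat_bp")
  out
}

#' Remove wild-type alleles by total repeat length
#'
#' Reads whose total repeat content is below `min_total_bp` (default 800 bp,
#' strict `<`) originate from the short wild-type allele and are removed
#' before structure summarization.
#'
#' @param records data.frame with a `total_repeat_bp` column (e.g. from
#'   [count_motifs()]).
#' @param min_total_bp threshold; rows with `total_repeat_bp >= min_total_bp`
#'   are kept.
#' @return the surviving rows, order preserved; removed count is logged.
#' @export
filter_wildtype <- function(records, min_total_bp = 800) {
  stopifnot("total_repeat_bp" %in% names(records))
  keep <- records$total_repeat_bp >= min_total_bp
  message(sum(!keep), " wild-type read(s) removed (<", min_total_bp,
          " bp repeat); ", sum(keep), " kept")
  records[keep, , drop = FALSE]
}

#' Detect reverse-strand TTCCA miscall artifacts
#'
#' Some basecallers systematically miscall large TTTTA/TTTCA tracts as TTCCA
#' on reads mapping to the reverse strand.  A read is flagged when it mapped
#' to the reverse strand AND its TTCCA run content exceeds `min_fraction` of
#' the combined TTCCA + TTTCA + TTTTA run content.  Flagged reads are
#' reported, not silently dropped.
#'
#' @param records data.frame with `seq` (reference-forward orientation) and
#'   `strand` columns.
#' @param min_fraction artifact fraction threshold (strict `>`).
#' @return logical vector, one element per read; `FALSE` with a warning for
#'   reads of unknown strand.
#' @export
detect_miscall_artifact <- function(records, min_fraction = 0.5) {
  stopifnot(all(c("seq", "strand") %in% names(records)))
  motifs <- as_motif_list(c("TTCCA", "TTTCA", "TTTTA"))
  keys <- vapply(motifs, `[[`, character(1), "canonical_key")
  if (any(records$strand == "unknown"))
    warning(sum(records$strand == "unknown"),
            " read(s) of unknown strand treated as non-artifact", call. = FALSE)
  flag <- vapply(seq_len(nrow(records)), function(i) {
    if (records$strand[i] != "reverse") return(FALSE)
    p <- profile_read(i, records$seq[i], motifs)
    tot <- sum(p$per_motif_bp[keys])
    tot > 0 && p$per_motif_bp[[keys[1]]] > min_fraction * tot
  }, logical(1))
  if (any(flag))
    message(sum(flag), " read(s) flagged as reverse-strand TTCCA miscall artifacts")
  flag
}

# -- segmentation --------------------------------------------------------------

# per-position best-phase windowed match fraction for one motif
.motif_score <- function(r, motif, window_copies, both_strands) {
  n <- length(r)
  k <- motif$length
  w <- window_copies * k
  half <- w %/% 2L
  idx <- seq_len(n)
  lo <- pmax(idx - half, 1L)
  hi <- pmin(idx + half, n)
  len <- hi - lo + 1L
  tmpls <- rotations(motif$display)
  if (both_strands) tmpls <- unique(c(tmpls, rotations(revcomp(motif$display))))
  best <- rep(0, n)
  for (t in tmpls) {
    tv <- rep(charToRaw(t), length.out = n)
    cs <- c(0L, cumsum(as.integer(r == tv)))
    best <- pmax(best, (cs[hi + 1L] - cs[lo]) / len)
  }
  best
}

#' Segment a long read into ordered motif blocks
#'
#' Noise-tolerant decomposition of a read into an ordered sequence of motif
#' blocks, e.g. `"(TTTTA)102-(TTTCA)98-(TTTTA)95-(TTGTA)640"`.  Each position
#' is assigned the motif whose periodic template (best phase over all
#' rotations) matches best within a sliding window of `window_copies` motif
#' copies; labels are majority-smoothed, run-length encoded, adjacent blocks
#' of the same motif are merged, blocks shorter than `min_block_copies`
#' copies are dropped into `unassigned_bp`, and block boundaries are refined
#' against the exact maximal tandem runs so that on error-free input the
#' result equals the exact run decomposition.
#'
#' @param x sequence string, or a record (list/one-row data.frame) with `seq`
#'   and optionally `read_id`.
#' @param motifs candidate motifs (may include the 15 bp composite
#'   `TTTTATTTTATTTCA`; which motifs are supplied changes the decomposition).
#' @param window_copies voting window size in motif copies.
#' @param min_block_copies minimum block size in copies; smaller blocks are
#'   dropped into `unassigned_bp`.
#' @param min_score minimum windowed match fraction for a position to be
#'   assigned at all (flanks and junk stay unassigned).
#' @param interruption_max_copies embedded tracts of at most this many copies
#'   sandwiched inside a single other-motif tract are reported in the
#'   `interruptions` table instead of as blocks.
#' @param both_strands also match reverse-complement rotations (off by
#'   default: records are expected in reference-forward orientation).
#' @param read_id read identifier (overrides the record's).
#' @return object of class `block_segmentation`: `read_id`, `read_length`,
#'   `blocks` (data.frame `motif`, `canonical`, `start`, `end`, `bp`,
#'   `copies`), `interruptions`, `unassigned_bp`, `total_repeat_bp`,
#'   `structure_string`.
#' @export
segment_read <- function(x, motifs, window_copies = 3, min_block_copies = 2,
                         min_score = 0.6, interruption_max_copies = 3,
                         both_strands = FALSE, read_id = NULL) {
  motifs <- as_motif_list(motifs)
  if (is.character(x)) {
    seq <- x
    if (is.null(read_id)) read_id <- "read"
  } else {
    seq <- x$seq
    if (is.null(read_id)) read_id <- if (!is.null(x$read_id)) x$read_id else "read"
  }
  stopifnot(length(seq) == 1L)
  n <- nchar(seq)
  mlens <- vapply(motifs, `[[`, integer(1), "length")
  disp <- vapply(motifs, `[[`, character(1), "display")
  keys <- vapply(motifs, `[[`, character(1), "canonical_key")

  empty_blocks <- data.frame(motif = character(0), canonical = character(0),
                             start = integer(0), end = integer(0),
                             bp = integer(0), copies = integer(0))
  no_interruptions <- data.frame(motif = character(0), start = integer(0),
                                 end = integer(0), copies = integer(0))
  mk <- function(blocks, unassigned, interruptions = no_interruptions) {
    structure(list(read_id = read_id, read_length = n, blocks = blocks,
                   interruptions = interruptions,
                   unassigned_bp = as.integer(unassigned),
                   total_repeat_bp = as.integer(sum(blocks$bp)),
                   structure_string = format_config(blocks)),
              class = "block_segmentation")
  }
  if (n == 0L) return(mk(empty_blocks, 0L))

  r <- charToRaw(seq)
  sc <- vapply(motifs, .motif_score, numeric(n),
               r = r, window_copies = window_copies, both_strands = both_strands)
  sc <- matrix(sc, nrow = n)
  lab <- max.col(sc, ties.method = "first")
  bestv <- sc[cbind(seq_len(n), lab)]
  lab[bestv < min_score] <- 0L

  # majority smoothing over a window of two shortest-motif copies
  sm <- 2L * min(mlens) + 1L
  if (n > sm) {
    half <- sm %/% 2L
    idx <- seq_len(n)
    lo <- pmax(idx - half, 1L); hi <- pmin(idx + half, n)
    cnt <- vapply(c(seq_along(motifs), 0L), function(l) {
      cs <- c(0L, cumsum(as.integer(lab == l)))
      cs[hi + 1L] - cs[lo]
    }, integer(n))
    pick <- max.col(matrix(cnt, nrow = n), ties.method = "first")
    lab <- c(seq_along(motifs), 0L)[pick]
  }

  # exact maximal runs, used to validate candidate blocks and refine
  # boundaries
  runs <- find_runs(seq, motifs, both_strands = both_strands)
  anchors <- runs[runs$bp >= min_block_copies * nchar(runs$motif), , drop = FALSE]

  # run-length encode, then iteratively drop sub-minimum or unanchored
  # blocks and merge.  A block must contain an exact tandem run of at least
  # min_block_copies copies of its motif: isolated basecall errors inside a
  # long tract of another motif mimic 1-2 copies of a different motif but
  # cannot produce an exact multi-copy run, so this rejects them without
  # touching genuine blocks.
  rl <- rle(lab)
  ends <- cumsum(rl$lengths)
  segs <- data.frame(label = rl$values, start = ends - rl$lengths, end = ends)
  segs <- segs[segs$label != 0L, , drop = FALSE]
  dropped <- 0L
  repeat {
    if (nrow(segs) == 0L) break
    anchored <- vapply(seq_len(nrow(segs)), function(i) {
      a <- anchors[anchors$canonical == keys[segs$label[i]], , drop = FALSE]
      any(a$start < segs$end[i] & a$end > segs$start[i])
    }, logical(1))
    small <- !anchored |
      (segs$end - segs$start) < min_block_copies * mlens[segs$label]
    if (any(small)) {
      dropped <- dropped + sum(segs$end[small] - segs$start[small])
      segs <- segs[!small, , drop = FALSE]
    }
    if (nrow(segs) > 1L) {
      same <- c(FALSE, segs$label[-1] == segs$label[-nrow(segs)])
      if (any(same)) {
        grp <- cumsum(!same)
        segs <- data.frame(
          label = segs$label[!same],
          start = tapply(segs$start, grp, min),
          end = tapply(segs$end, grp, max))
        next  # merged spans may change nothing else, but re-check sizes
      }
    }
    if (!any(small)) break
  }
  if (nrow(segs) == 0L) return(mk(empty_blocks, dropped))
  rownames(segs) <- NULL

  # interruption extraction: a tiny block sandwiched between two blocks of
  # one same motif is reported as an interruption of that tract, not as a
  # structure block (at nanopore-like error rates a double miscall inside a
  # long tract produces exact 2-copy mimics of another motif in a few
  # percent of reads; micro-tracts this small cannot be told apart from
  # them, so they must not inflate the block structure)
  interruptions <- no_interruptions
  repeat {
    if (nrow(segs) < 3L) break
    cp <- round((segs$end - segs$start) / mlens[segs$label])
    mid <- seq_len(nrow(segs))[-c(1L, nrow(segs))]
    sand <- mid[segs$label[mid - 1L] == segs$label[mid + 1L] &
                  segs$label[mid] != segs$label[mid - 1L] &
                  cp[mid] <= interruption_max_copies]
    if (length(sand) == 0L) break
    i <- sand[1]
    interruptions <- rbind(interruptions, data.frame(
      motif = disp[segs$label[i]], start = as.integer(segs$start[i]),
      end = as.integer(segs$end[i]), copies = as.integer(cp[i])))
    segs$end[i - 1L] <- segs$end[i + 1L]
    segs <- segs[-c(i, i + 1L), , drop = FALSE]
  }
  rownames(segs) <- NULL

  # snap the outer edges to the exact-run envelope of the terminal blocks:
  # window voting bleeds a few bp into non-repeat flank, whereas the maximal
  # runs end exactly where periodic content ends
  if (nrow(runs) > 0L) {
    fr <- runs[runs$canonical == keys[segs$label[1]] &
                 runs$start < segs$end[1] & runs$end > segs$start[1], , drop = FALSE]
    if (nrow(fr) > 0L) segs$start[1] <- min(fr$start)
    nlast <- nrow(segs)
    lr <- runs[runs$canonical == keys[segs$label[nlast]] &
                 runs$start < segs$end[nlast] & runs$end > segs$start[nlast], ,
               drop = FALSE]
    if (nrow(lr) > 0L) segs$end[nlast] <- max(lr$end)
  }

  # refine boundaries against exact maximal runs: on clean input the true
  # junction is the midpoint of the bridge shared by the two flanking runs
  if (nrow(segs) > 1L && nrow(runs) > 0L) {
    for (i in seq_len(nrow(segs) - 1L)) {
      a <- segs$label[i]; b <- segs$label[i + 1L]
      wpad <- 2L * (mlens[a] + mlens[b])
      wlo <- segs$end[i] - wpad; whi <- segs$start[i + 1L] + wpad
      ra <- runs[runs$canonical == keys[a] & runs$end >= wlo &
                   runs$end <= whi & runs$start < segs$start[i + 1L], , drop = FALSE]
      rb <- runs[runs$canonical == keys[b] & runs$start >= wlo &
                   runs$start <= whi & runs$end > segs$end[i], , drop = FALSE]
      if (nrow(ra) == 0L || nrow(rb) == 0L) next
      cut <- (max(ra$end) + min(rb$start)) %/% 2L
      cut <- max(min(cut, segs$end[i + 1L] - 1L), segs$start[i] + 1L)
      segs$end[i] <- cut
      segs$start[i + 1L] <- cut
    }
  }

  blocks <- data.frame(motif = disp[segs$label],
                       canonical = keys[segs$label],
                       start = as.integer(segs$start),
                       end = as.integer(segs$end),
                       bp = as.integer(segs$end - segs$start),
                       copies = as.integer(round((segs$end - segs$start) /
                                                   mlens[segs$label])))
  span_un <- (max(blocks$end) - min(blocks$start)) - sum(blocks$bp)
  mk(blocks, span_un, interruptions)
}

#' @export
print.block_segmentation <- function(x, ...) {
  cat(sprintf("<block_segmentation> %s (%d bp): %s  [%d bp unassigned]\n",
              x$read_id, x$read_length,
              if (nzchar(x$structure_string)) x$structure_string else "<empty>",
              x$unassigned_bp))
  invisible(x)
}

#' Segment many reads
#'
#' @param records data.frame with `read_id` and `seq`.
#' @inheritParams segment_read
#' @return list of `block_segmentation`.
#' @export
segment_reads <- function(records, motifs, window_copies = 3,
                          min_block_copies = 2, min_score = 0.6,
                          interruption_max_copies = 3, both_strands = FALSE) {
  motifs <- as_motif_list(motifs)
  Map(function(id, s) segment_read(s, motifs, window_copies, min_block_copies,
                                   min_score, interruption_max_copies,
                                   both_strands, read_id = id),
      records$read_id, records$seq)
}

#' Consensus repeat structure across reads
#'
#' The modal block order (sequence of motif canonical keys) across reads,
#' with per-block median bp, median copies and copy-count MAD (mosaicism /
#' PCR-bias dispersion); reads disagreeing with the modal order are counted
#' and reported, not averaged in.
#'
#' @param segs non-empty list of `block_segmentation`.
#' @return object of class `consensus_structure`: `structure_string` (modal
#'   order with median copies), `n_reads`, `n_discordant`, `blocks`
#'   (data.frame `motif`, `median_bp`, `median_copies`, `mad_copies`).
#' @export
consensus_structure <- function(segs) {
  if (length(segs) == 0L) stop("no segmentations supplied", call. = FALSE)
  orders <- vapply(segs, function(s) paste(s$blocks$canonical, collapse = ">"),
                   character(1))
  tab <- sort(table(orders), decreasing = TRUE)
  modal <- names(tab)[1]
  conc <- segs[orders == modal]
  nb <- nrow(conc[[1]]$blocks)
  if (nb == 0L) stop("modal structure has no blocks", call. = FALSE)
  bp <- vapply(conc, function(s) s$blocks$bp, numeric(nb))
  cp <- vapply(conc, function(s) s$blocks$copies, numeric(nb))
  bp <- matrix(bp, nrow = nb); cp <- matrix(cp, nrow = nb)
  blocks <- data.frame(
    motif = conc[[1]]$blocks$motif,
    median_bp = apply(bp, 1, stats::median),
    median_copies = apply(cp, 1, stats::median),
    mad_copies = apply(cp, 1, stats::mad))
  structure(list(
    structure_string = paste(sprintf("(%s)%d", blocks$motif,
                                     as.integer(round(blocks$median_copies))),
                             collapse = "-"),
    n_reads = length(segs),
    n_discordant = length(segs) - length(conc),
    blocks = blocks), class = "consensus_structure")
}

#' @export
print.consensus_structure <- function(x, ...) {
  cat(sprintf("<consensus_structure> %s\n", x$structure_string))
  cat(sprintf("  %d read(s), %d discordant with modal block order\n",
              x$n_reads, x$n_discordant))
  print(x$blocks)
  invisible(x)
}

#' Waterfall summary of segmented reads
#'
#' Orders reads by total repeat bp (descending, ties by read id) -- the row
#' order of a waterfall plot -- and tabulates per-motif copy-count
#' distributions.
#'
#' @param segs non-empty list of `block_segmentation`.
#' @return object of class `waterfall_summary`: `rows` (data.frame `read_id`,
#'   `total_repeat_bp`, `structure_string`, in waterfall order), `blocks`
#'   (long data.frame of block tracks per read) and `motif_stats`
#'   (per-motif `min`/`median`/`max` copies per read).
#' @export
waterfall <- function(segs) {
  if (length(segs) == 0L) stop("no segmentations supplied", call. = FALSE)
  rows <- data.frame(
    read_id = vapply(segs, `[[`, character(1), "read_id"),
    total_repeat_bp = vapply(segs, `[[`, integer(1), "total_repeat_bp"),
    structure_string = vapply(segs, `[[`, character(1), "structure_string"))
  ord <- order(-rows$total_repeat_bp, rows$read_id)
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  segs <- segs[ord]
  blocks <- do.call(rbind, lapply(seq_along(segs), function(i) {
    b <- segs[[i]]$blocks
    if (nrow(b) == 0L) return(NULL)
    data.frame(row = i, read_id = segs[[i]]$read_id, b)
  }))
  per_motif <- if (is.null(blocks)) NULL else
    split(blocks, blocks$motif)
  motif_stats <- if (is.null(per_motif)) NULL else do.call(rbind, lapply(
    names(per_motif), function(m) {
      per_read <- tapply(per_motif[[m]]$copies, per_motif[[m]]$read_id, sum)
      data.frame(motif = m, n_reads = length(per_read),
                 min_copies = min(per_read),
                 median_copies = stats::median(per_read),
                 max_copies = max(per_read))
    }))
  structure(list(rows = rows, blocks = blocks, motif_stats = motif_stats),
            class = "waterfall_summary")
}

#' @export
print.waterfall_summary <- function(x, ...) {
  cat(sprintf("<waterfall_summary> %d read(s)\n", nrow(x$rows)))
  print(utils::head(x$rows, 10))
  if (!is.null(x$motif_stats)) print(x$motif_stats)
  invisible(x)
}

#' Write / read the waterfall row table as TSV
#'
#' @param ws a `waterfall_summary`.
#' @param path output TSV path.
#' @param config optional configuration recorded in the provenance header.
#' @return the reader returns the rows data.frame.
#' @export
write_waterfall_tsv <- function(ws, path, config = NULL) {
  stopifnot(inherits(ws, "waterfall_summary"))
  write_tsv_prov(ws$rows, path, config)
}

#' @rdname write_waterfall_tsv
#' @export
read_waterfall_tsv <- function(path) read_tsv_prov(path)

#' Plot a waterfall of motif-coloured read tracks
#'
#' One horizontal bar per read (waterfall order: longest repeat on top), each
#' motif block drawn in its own colour.  Intended as a quick visual check of
#' repeat structure and mosaicism, not publication graphics.
#'
#' @param ws a `waterfall_summary`.
#' @param path optional PNG path; when `NULL`, draws on the current device.
#' @param colors named vector motif display -> colour; sensible defaults for
#'   the FAME pentamer motifs.
#' @return invisibly, the colour map used.
#' @export
plot_waterfall <- function(ws, path = NULL, colors = NULL) {
  stopifnot(inherits(ws, "waterfall_summary"))
  if (is.null(ws$blocks)) stop("no blocks to plot", call. = FALSE)
  motifs <- unique(ws$blocks$motif)
  defaults <- c(TTTTA = "#4D7EBF", TTTCA = "#D9534F", TTGTA = "#5CB85C",
                TTCCA = "#B06AB3", TTTTATTTTATTTCA = "#F0AD4E")
  cols <- stats::setNames(
    ifelse(motifs %in% names(defaults), defaults[motifs],
           grDevices::rainbow(length(motifs))), motifs)
  if (!is.null(colors)) cols[names(colors)] <- colors
  if (!is.null(path)) grDevices::png(path, width = 900, height = 120 +
                                       24 * nrow(ws$rows))
  nr <- nrow(ws$rows)
  graphics::plot(NULL, xlim = c(0, max(ws$rows$total_repeat_bp) * 1.02),
                 ylim = c(0, nr + 1), xlab = "repeat bp", ylab = "",
                 yaxt = "n", main = "repeat structure waterfall")
  for (i in seq_len(nr)) {
    b <- ws$blocks[ws$blocks$row == i, , drop = FALSE]
    if (nrow(b) == 0L) next
    x0 <- cumsum(c(0, b$bp))
    graphics::rect(x0[-length(x0)], nr - i + 0.6, x0[-1], nr - i + 1.4,
                   col = cols[b$motif], border = NA)
  }
  graphics::legend("bottomright", legend = names(cols), fill = cols, bty = "n")
  if (!is.null(path)) grDevices::dev.off()
  invisible(cols)
}

#' Full long-read decomposition workflow
#'
#' Extract -> count -> wild-type filter -> artifact filter -> segment ->
#' consensus + waterfall, in one call.
#'
#' @param read_table alignment-derived read table (see
#'   [extract_region_reads()]); or pre-extracted records (`read_id`, `seq`,
#'   `strand`) when `region` is `NULL`.
#' @param motifs target motifs (include TTCCA to enable artifact detection).
#' @param region target region string, or `NULL` if records are pre-extracted.
#' @param min_total_bp wild-type filter threshold.
#' @param artifact_fraction TTCCA artifact fraction threshold; `NULL`
#'   disables artifact filtering.
#' @param ... passed to [segment_read()].
#' @return list with `counts`, `kept` (post-filter counts), `artifact`
#'   (logical per kept read), `segments`, `consensus`, `waterfall`.
#' @export
decompose_reads <- function(read_table, motifs, region = NULL,
                            min_total_bp = 800, artifact_fraction = 0.5, ...) {
  motifs <- as_motif_list(motifs)
  records <- if (is.null(region)) read_table else
    extract_region_reads(read_table, region)
  counts <- count_motifs(records, motifs)
  kept <- filter_wildtype(counts, min_total_bp)
  records <- records[match(kept$read_id, records$read_id), , drop = FALSE]
  art <- if (!is.null(artifact_fraction) && "strand" %in% names(records))
    detect_miscall_artifact(records, artifact_fraction)
  else rep(FALSE, nrow(records))
  segs <- segment_reads(records[!art, , drop = FALSE], motifs, ...)
  list(counts = counts, kept = kept, artifact = art, segments = segs,
       consensus = if (length(segs)) consensus_structure(segs) else NULL,
       waterfall = if (length(segs)) waterfall(segs) else NULL)
}
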