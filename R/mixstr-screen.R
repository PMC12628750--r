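# The mixSTR screen: read pairs where both mates are (nearly) pure repeat and
# the pair jointly carries substantial tracts of EVERY target motif are
# evidence of adjacent expansions of different motifs; samples with enough
# such pairs are flagged for targeted follow-up.

#' Classify a read pair as mixed-motif expansion evidence
#'
#' A pair qualifies when both reads carry more than `min_read_bp` of total
#' repeat sequence (default `> 125` bp) AND, for every target motif, the pair
#' in aggregate carries at least `min_motif_bp` of that motif (default
#' `>= 50` bp across the pair).  The per-motif criterion applying to *all*
#' target motifs is the point of the method: a pair pure in a single motif
#' never qualifies.
#'
#' @param p1,p2 `read_repeat_profile` objects computed over (at least) the
#'   target motif set.
#' @param target_motifs motifs the pair must jointly contain.
#' @param min_read_bp per-read total repeat threshold (strict `>`).
#' @param min_motif_bp per-motif pair-aggregate threshold (`>=`).
#' @return object of class `pair_classification`: list with `pair_id`,
#'   `qualifies`, `reason` (one of `ok`, `read_below_min`, `motif_below_min`),
#'   `per_motif_pair_bp`, `read1_total_bp`, `read2_total_bp`.  Symmetric in
#'   `(p1, p2)`.
#' @export
classify_pair <- function(p1, p2, target_motifs, min_read_bp = 125,
                          min_motif_bp = 50) {
  stopifnot(inherits(p1, "read_repeat_profile"),
            inherits(p2, "read_repeat_profile"))
  target_motifs <- as_motif_list(target_motifs)
  keys <- vapply(target_motifs, `[[`, character(1), "canonical_key")
  if (!all(keys %in% names(p1$per_motif_bp)) ||
      !all(keys %in% names(p2$per_motif_bp)))
    stop("profiles were not computed over the target motif set", call. = FALSE)
  pair_bp <- p1$per_motif_bp[keys] + p2$per_motif_bp[keys]
  reads_ok <- p1$total_repeat_bp > min_read_bp && p2$total_repeat_bp > min_read_bp
  motifs_ok <- all(pair_bp >= min_motif_bp)
  structure(list(
    pair_id = p1$read_id,
    qualifies = reads_ok && motifs_ok,
    reason = if (!reads_ok) "read_below_min"
             else if (!motifs_ok) "motif_below_min" else "ok",
    per_motif_pair_bp = pair_bp,
    read1_total_bp = p1$total_repeat_bp,
    read2_total_bp = p2$total_repeat_bp), class = "pair_classification")
}

#' @export
print.pair_classification <- function(x, ...) {
  cat(sprintf("<pair_classification> %s: %s (%s)\n", x$pair_id,
              if (x$qualifies) "qualifies" else "does not qualify", x$reason))
  invisible(x)
}

# internal: classify a table of sequence pairs; returns per-pair data.frame
.classify_pair_table <- function(pairs, target_motifs, min_read_bp,
                                 min_motif_bp, min_fraction = NULL) {
  target_motifs <- as_motif_list(target_motifs)
  n <- nrow(pairs)
  ids <- if ("pair_id" %in% names(pairs)) pairs$pair_id else
    sprintf("pair%06d", seq_len(n))
  keys <- vapply(target_motifs, `[[`, character(1), "canonical_key")
  disp <- vapply(target_motifs, `[[`, character(1), "display")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pr1 <- profile_read(ids[i], pairs$read1[i], target_motifs)
    pr2 <- profile_read(ids[i], pairs$read2[i], target_motifs)
    cl <- classify_pair(pr1, pr2, target_motifs, min_read_bp, min_motif_bp)
    by <- if (cl$qualifies) "bp" else "none"
    if (!is.null(min_fraction)) {
      frac_ok <- all(vapply(keys, function(k)
        pr1$per_motif_bp[[k]] / pr1$read_length > min_fraction &&
        pr2$per_motif_bp[[k]] / pr2$read_length > min_fraction, logical(1)))
      if (frac_ok) by <- if (by == "bp") "both" else "fraction"
    }
    row <- data.frame(pair_id = ids[i],
                      qualifies = by != "none",
                      reason = cl$reason,
                      qualified_by = by,
                      read1_total_bp = cl$read1_total_bp,
                      read2_total_bp = cl$read2_total_bp)
    for (j in seq_along(keys))
      row[[paste0(disp[j], "_pair_bp")]] <- unname(cl$per_motif_pair_bp[keys[j]])
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}

#' Screen one sample's read pairs for mixed-motif expansion evidence
#'
#' Counts qualifying pairs (see [classify_pair()]) and flags the sample when
#' at least `min_pairs` qualify (default 3, the "at least three read pairs"
#' follow-up rule).  Optionally a purity criterion can be OR-ed in: a pair
#' also qualifies when both reads individually exceed `min_fraction` of their
#' length in every target motif (the `> 90%` in-repeat-read style criterion
#' used for single-motif screens); the `qualified_by` column records which
#' criterion fired (`bp`, `fraction`, `both`).
#'
#' @param pairs data.frame with columns `read1`, `read2` (sequences) and
#'   optionally `pair_id`; order does not affect the result.
#' @param target_motifs target motif set.
#' @param min_read_bp,min_motif_bp thresholds, see [classify_pair()].
#' @param min_pairs sample flagging threshold (`>=`).
#' @param min_fraction optional per-read repeat-fraction criterion (strict
#'   `>`), OR-ed with the bp criteria; `NULL` disables it.
#' @param sample_id sample identifier.
#' @return object of class `sample_screen_result`: list with `sample_id`,
#'   `qualifying_pairs`, `flagged`, `min_pairs` and the per-pair table in
#'   `$pairs`.
#' @export
screen_sample <- function(pairs, target_motifs, min_read_bp = 125,
                          min_motif_bp = 50, min_pairs = 3,
                          min_fraction = NULL, sample_id = "sample") {
  target_motifs <- as_motif_list(target_motifs)
  if (is.null(pairs) || nrow(pairs) == 0L) {
    tab <- NULL
    nq <- 0L
  } else {
    stopifnot(all(c("read1", "read2") %in% names(pairs)))
    tab <- .classify_pair_table(pairs, target_motifs, min_read_bp,
                                min_motif_bp, min_fraction)
    nq <- sum(tab$qualifies)
  }
  structure(list(sample_id = sample_id, qualifying_pairs = nq,
                 flagged = nq >= min_pairs, min_pairs = min_pairs,
                 pairs = tab), class = "sample_screen_result")
}

#' @export
print.sample_screen_result <- function(x, ...) {
  cat(sprintf("<sample_screen_result> %s: %d qualifying pair(s), %s (min %d)\n",
              x$sample_id, x$qualifying_pairs,
              if (x$flagged) "FLAGGED" else "not flagged", x$min_pairs))
  invisible(x)
}

#' Screen a cohort of samples
#'
#' @param samples named list of per-sample pair data.frames (see
#'   [screen_sample()]), or a manifest data.frame with columns `sample_id`,
#'   `r1`, `r2` naming paired FASTQ files.
#' @inheritParams screen_sample
#' @return data.frame with one row per sample (`sample_id`,
#'   `qualifying_pairs`, `flagged`), ordered by `sample_id`.
#' @export
screen_cohort <- function(samples, target_motifs, min_read_bp = 125,
                          min_motif_bp = 50, min_pairs = 3,
                          min_fraction = NULL) {
  target_motifs <- as_motif_list(target_motifs)
  if (is.data.frame(samples)) {
    stopifnot(all(c("sample_id", "r1", "r2") %in% names(samples)))
    ids <- samples$sample_id
    getter <- function(i) read_fastq_pairs(samples$r1[i], samples$r2[i])
  } else {
    if (length(samples) == 0L) stop("cohort must contain >= 1 sample", call. = FALSE)
    ids <- names(samples)
    if (is.null(ids)) stop("sample list must be named by sample_id", call. = FALSE)
    getter <- function(i) samples[[i]]
  }
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  res <- lapply(seq_along(ids), function(i)
    screen_sample(getter(i), target_motifs, min_read_bp, min_motif_bp,
                  min_pairs, min_fraction, sample_id = ids[i]))
  out <- data.frame(
    sample_id = ids,
    qualifying_pairs = vapply(res, `[[`, integer(1), "qualifying_pairs"),
    flagged = vapply(res, `[[`, logical(1), "flagged"))
  out <- out[order(out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  message(sum(out$flagged), " of ", nrow(out), " sample(s) flagged")
  out
}

#' Read paired FASTQ files into a pair table
#'
#' Mates are paired by position; `/1`, `/2` and space-separated comment
#' suffixes are stripped from ids.  Gzipped input is handled transparently.
#'
#' @param r1,r2 FASTQ file paths.
#' @return data.frame with `pair_id`, `read1`, `read2`.
#' @export
read_fastq_pairs <- function(r1, r2) {
  s1 <- Biostrings::readDNAStringSet(r1, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(r2, format = "fastq")
  if (length(s1) != length(s2))
    stop("mate files differ in read count", call. = FALSE)
  ids <- sub("/[12]$", "", sub("[ \t].*$", "", names(s1)))
  data.frame(pair_id = ids, read1 = as.character(s1), read2 = as.character(s2))
}
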