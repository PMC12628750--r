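# Synthetic data: diploid repeat alleles (wild-type + complex expansions with
# optional mosaicism), Illumina-like 151 bp read pairs and nanopore-like
# noisy long reads with optional strand-biased TTCCA miscall artifacts.
# Every other module is tested against this generator's ground truth.

# evaluate expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Random DNA sequence
#'
#' @param n length in bp.
#' @param gc GC content.
#' @return DNA string.
#' @export
random_dna <- function(n, gc = 0.4) {
  if (n == 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Default synthetic flanking sequences
#'
#' Deterministic synthetic stand-ins for the reference flanks of a repeat
#' locus (no reference genome is downloaded): 500 bp each side, GC 0.4,
#' generated from a fixed internal seed so every call returns the same pair.
#'
#' @param length flank length in bp (each side).
#' @return list with `left` and `right` DNA strings.
#' @export
default_flanks <- function(length = 500) {
  with_seed(190538L, list(left = random_dna(length), right = random_dna(length)))
}

#' Define a (possibly mosaic) repeat allele
#'
#' @param config a `repeat_config` or configuration string (flanks in the
#'   config are ignored; the model's flanks are used).
#' @param flanks list with `left`/`right` DNA strings (default:
#'   [default_flanks()]).
#' @param mosaic_block index of the block whose copy number varies from read
#'   template to read template (e.g. an unstable TTGTA expansion), or `NULL`.
#' @param mosaic_dist copy-count distribution for the mosaic block:
#'   `list(family = "lognormal", meanlog =, sdlog =)` or
#'   `list(family = "discrete", values =, probs =)`.
#' @return object of class `allele_model`.
#' @export
allele_model <- function(config, flanks = NULL, mosaic_block = NULL,
                         mosaic_dist = NULL) {
  if (is.character(config)) config <- parse_config(config)
  stopifnot(inherits(config, "repeat_config"))
  if (is.null(flanks)) flanks <- default_flanks()
  if (!is.null(mosaic_block)) {
    stopifnot(mosaic_block >= 1, mosaic_block <= nrow(config$blocks))
    if (is.null(mosaic_dist))
      stop("mosaic_block set but no mosaic_dist given", call. = FALSE)
    stopifnot(mosaic_dist$family %in% c("lognormal", "discrete"))
  }
  structure(list(config = config, flanks = flanks,
                 mosaic_block = mosaic_block, mosaic_dist = mosaic_dist),
            class = "allele_model")
}

.draw_mosaic_copies <- function(dist) {
  cp <- switch(dist$family,
    lognormal = round(stats::rlnorm(1, dist$meanlog, dist$sdlog)),
    discrete = sample(dist$values, 1, prob = dist$probs))
  max(1L, as.integer(cp))
}

#' Realize one allele template
#'
#' Draws the mosaic block's copy number (if any) and synthesizes the full
#' allele sequence.  Uses the current RNG state; seed upstream for
#' reproducibility.
#'
#' @param model an `allele_model`, `repeat_config` or configuration string.
#' @return list with `seq` (flanks + repeat), `blocks` (ground-truth table:
#'   `motif`, `copies`, `bp`, `start`, `end` in 0-based read coordinates)
#'   and `config` (the realized `repeat_config`).
#' @export
simulate_allele <- function(model) {
  if (!inherits(model, "allele_model")) model <- allele_model(model)
  blocks <- model$config$blocks
  if (!is.null(model$mosaic_block)) {
    cp <- .draw_mosaic_copies(model$mosaic_dist)
    blocks$copies[model$mosaic_block] <- cp
    blocks$bp[model$mosaic_block] <- cp * nchar(blocks$motif[model$mosaic_block])
  }
  config <- repeat_config(blocks[, c("motif", "copies")],
                          left_flank = model$flanks$left,
                          right_flank = model$flanks$right)
  b <- config$blocks
  off <- nchar(model$flanks$left)
  b$start <- off + c(0L, cumsum(b$bp))[seq_len(nrow(b))]
  b$end <- b$start + b$bp
  list(seq = config_to_sequence(config), blocks = b, config = config)
}

# -- short reads ---------------------------------------------------------------

#' Illumina-like paired-end simulation parameters
#'
#' @param read_length read length in bp (151, the NovaSeq default here).
#' @param fragment_mean,fragment_sd insert-size distribution (bp).
#' @param coverage target fold coverage per allele.
#' @param sub_rate per-base substitution rate.
#' @param seed RNG seed.
#' @return object of class `short_read_spec`.
#' @export
short_read_spec <- function(read_length = 151, fragment_mean = 400,
                            fragment_sd = 60, coverage = 30,
                            sub_rate = 0.001, seed = 1) {
  stopifnot(read_length <= fragment_mean, sub_rate >= 0, sub_rate < 1)
  structure(list(read_length = as.integer(read_length),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 coverage = coverage, sub_rate = sub_rate,
                 seed = as.integer(seed)), class = "short_read_spec")
}

.apply_subs <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(ch)) < rate)
    if (length(hit)) {
      alt <- c("A", "C", "G", "T")
      ch[hit] <- vapply(ch[hit], function(b)
        sample(setdiff(alt, b), 1), character(1))
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate Illumina-like read pairs from a diploid individual
#'
#' Fragments are drawn uniformly along each allele, in numbers proportional
#' to allele length at the requested coverage; mates are the fragment ends,
#' read 2 reverse-complemented.  Deterministic given `spec$seed`.
#'
#' @param alleleA,alleleB allele sequences (strings), or `allele_model`s
#'   (realized once each).
#' @param spec a [short_read_spec()].
#' @return list with `pairs` (data.frame `pair_id`, `read1`, `read2`) and
#'   `truth` (data.frame `pair_id`, `allele`, `frag_start`, `frag_end`,
#'   0-based allele coordinates).
#' @export
simulate_short_pairs <- function(alleleA, alleleB, spec = short_read_spec()) {
  get_seq <- function(a) if (is.character(a)) a else simulate_allele(a)$seq
  with_seed(spec$seed, {
    seqs <- c(A = get_seq(alleleA), B = get_seq(alleleB))
    rl <- spec$read_length
    all_pairs <- list(); all_truth <- list()
    for (al in names(seqs)) {
      s <- seqs[[al]]
      len <- nchar(s)
      if (len < rl)
        stop("allele ", al, " (", len, " bp) is shorter than the read length",
             call. = FALSE)
      nfrag <- max(0L, as.integer(round(spec$coverage * len / (2 * rl))))
      if (nfrag == 0L) next
      fl <- as.integer(round(stats::rnorm(nfrag, spec$fragment_mean,
                                          spec$fragment_sd)))
      fl <- pmax(fl, rl)
      too_long <- fl > len
      tries <- 0L
      while (any(too_long)) {  # resample fragments longer than the allele
        warning(sum(too_long), " fragment(s) longer than allele ", al,
                "; resampled", call. = FALSE)
        fl[too_long] <- pmax(as.integer(round(stats::rnorm(
          sum(too_long), spec$fragment_mean, spec$fragment_sd))), rl)
        too_long <- fl > len
        tries <- tries + 1L
        if (tries > 50L) {  # allele much shorter than the insert distribution
          fl[too_long] <- len
          too_long <- FALSE
        }
      }
      start <- as.integer(floor(stats::runif(nfrag, 0, len - fl + 1)))
      frag <- substring(s, start + 1L, start + fl)
      r1 <- .apply_subs(substr(frag, 1L, rl), spec$sub_rate)
      r2 <- .apply_subs(revcomp(substring(frag, fl - rl + 1L, fl)),
                        spec$sub_rate)
      ids <- sprintf("%s_frag%05d", al, seq_len(nfrag))
      all_pairs[[al]] <- data.frame(pair_id = ids, read1 = r1, read2 = r2)
      all_truth[[al]] <- data.frame(pair_id = ids, allele = al,
                                    frag_start = start, frag_end = start + fl)
    }
    list(pairs = do.call(rbind, c(all_pairs, list(NULL))),
         truth = do.call(rbind, c(all_truth, list(NULL))))
  })
}

# -- long reads ----------------------------------------------------------------

#' Nanopore-like amplicon simulation parameters
#'
#' @param coverage number of full-length amplicon reads per allele.
#' @param sub_rate,ins_rate,del_rate per-base error rates.
#' @param reverse_prob probability a read is sequenced from the reverse
#'   strand.
#' @param artifact_rate fraction of reverse-strand reads receiving the TTCCA
#'   miscall corruption.
#' @param artifact_tract_frac fraction of each TTTTA/TTTCA block's copies
#'   rewritten as TTCCA in a corrupted read (contiguous central tract).
#' @param seed RNG seed.
#' @return object of class `long_read_spec`.
#' @export
long_read_spec <- function(coverage = 50, sub_rate = 0.02, ins_rate = 0.01,
                           del_rate = 0.01, reverse_prob = 0.5,
                           artifact_rate = 0, artifact_tract_frac = 0.9,
                           seed = 1) {
  stopifnot(sub_rate >= 0, sub_rate < 1, ins_rate >= 0, ins_rate < 1,
            del_rate >= 0, del_rate < 1, artifact_rate >= 0, artifact_rate <= 1)
  structure(list(coverage = as.integer(coverage), sub_rate = sub_rate,
                 ins_rate = ins_rate, del_rate = del_rate,
                 reverse_prob = reverse_prob, artifact_rate = artifact_rate,
                 artifact_tract_frac = artifact_tract_frac,
                 seed = as.integer(seed)), class = "long_read_spec")
}

# rewrite the central `frac` of each TTTTA/TTTCA block's copies as TTCCA,
# mimicking basecallers miscalling large tracts on one strand
.corrupt_ttcca <- function(blocks, frac) {
  pieces <- character(nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    m <- blocks$motif[i]; cp <- blocks$copies[i]
    if (!m %in% c("TTTTA", "TTTCA")) {
      pieces[i] <- strrep(m, cp)
    } else {
      bad <- as.integer(round(frac * cp))
      pre <- (cp - bad) %/% 2L
      pieces[i] <- paste0(strrep(m, pre), strrep("TTCCA", bad),
                          strrep(m, cp - pre - bad))
    }
  }
  paste(pieces, collapse = "")
}

.apply_long_errors <- function(seq, sub, ins, del) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  alt <- c("A", "C", "G", "T")
  keep <- stats::runif(n) >= del
  smut <- stats::runif(n) < sub
  hit <- which(keep & smut)
  if (length(hit))
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(alt, b), 1),
                      character(1))
  insmask <- stats::runif(n) < ins
  out <- ch
  out[!keep] <- ""
  if (any(insmask)) {
    nm <- sum(insmask)
    out[insmask] <- paste0(out[insmask], sample(alt, nm, replace = TRUE))
  }
  n_err <- c(sub = length(hit), ins = sum(insmask), del = sum(!keep))
  list(seq = paste(out, collapse = ""), n_err = n_err)
}

#' Simulate targeted long-read (amplicon) sequencing of a diploid locus
#'
#' Emits `coverage` full-length amplicon reads per allele.  Mosaic allele
#' models are re-realized per read template (each read draws its own copy
#' number for the mosaic block).  Reverse-strand reads are emitted
#' reverse-complemented, as a sequencer would, with the strand recorded in
#' the alignment-like table; optionally a fraction of reverse-strand reads
#' receive TTCCA miscall corruption of their TTTTA/TTTCA tracts before the
#' error process.
#'
#' @param alleleA,alleleB `allele_model`s (or `repeat_config`s /
#'   configuration strings; then no mosaicism and default flanks).
#' @param spec a [long_read_spec()].
#' @param locus a `locus_spec` providing the contig/interval written to the
#'   alignment-like table (default [fame3_locus()]).
#' @return list with `reads` (data.frame `read_id`, `seq` as sequenced),
#'   `align` (data.frame `read_id`, `contig`, `start`, `end`, `strand`,
#'   `seq`) and `truth` (data.frame `read_id`, `allele`, `strand`,
#'   `artifact`, `structure_string`, `total_repeat_bp`, `n_sub`, `n_ins`,
#'   `n_del`).
#' @export
simulate_long_reads <- function(alleleA, alleleB, spec = long_read_spec(),
                                locus = fame3_locus()) {
  as_model <- function(a) {
    if (inherits(a, "allele_model")) a
    else if (inherits(a, "repeat_config") ||
             (is.character(a) && grepl("^\\(", a))) allele_model(a)
    else stop("allele must be an allele_model, repeat_config or config string",
              call. = FALSE)
  }
  models <- list(A = as_model(alleleA), B = as_model(alleleB))
  with_seed(spec$seed, {
    reads <- list(); align <- list(); truth <- list()
    idx <- 0L
    for (al in names(models)) {
      for (j in seq_len(spec$coverage)) {
        idx <- idx + 1L
        tmpl <- simulate_allele(models[[al]])
        strand <- if (stats::runif(1) < spec$reverse_prob) "reverse" else "forward"
        artifact <- strand == "reverse" && stats::runif(1) < spec$artifact_rate
        body <- if (artifact)
          .corrupt_ttcca(tmpl$blocks, spec$artifact_tract_frac)
        else substr(tmpl$seq, nchar(models[[al]]$flanks$left) + 1L,
                    nchar(tmpl$seq) - nchar(models[[al]]$flanks$right))
        template <- paste0(models[[al]]$flanks$left, body,
                           models[[al]]$flanks$right)
        err <- .apply_long_errors(template, spec$sub_rate, spec$ins_rate,
                                  spec$del_rate)
        emitted <- if (strand == "reverse") revcomp(err$seq) else err$seq
        rid <- sprintf("%s_read%04d", al, idx)
        reads[[idx]] <- data.frame(read_id = rid, seq = emitted)
        align[[idx]] <- data.frame(
          read_id = rid, contig = locus$contig,
          start = locus$start - nchar(models[[al]]$flanks$left),
          end = locus$start + nchar(template) -
            nchar(models[[al]]$flanks$left),
          strand = strand, seq = emitted)
        truth[[idx]] <- data.frame(
          read_id = rid, allele = al, strand = strand, artifact = artifact,
          structure_string = format_config(tmpl$blocks),
          total_repeat_bp = sum(tmpl$blocks$bp),
          n_sub = err$n_err[["sub"]], n_ins = err$n_err[["ins"]],
          n_del = err$n_err[["del"]])
      }
    }
    list(reads = do.call(rbind, reads), align = do.call(rbind, align),
         truth = do.call(rbind, truth))
  })
}

# -- FASTQ output --------------------------------------------------------------

#' Write sequences as FASTQ
#'
#' Constant base quality (no stage of the toolkit consumes qualities).
#' Compression is inferred from a `.gz` suffix.
#'
#' @param ids,seqs read ids and sequences.
#' @param path output path.
#' @param quality constant quality character.
#' @return the path, invisibly.
#' @export
write_fastq <- function(ids, seqs, path, quality = "I") {
  x <- Biostrings::DNAStringSet(as.character(seqs))
  names(x) <- ids
  q <- Biostrings::BStringSet(strrep(quality, nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write simulated read pairs as paired FASTQ files
#'
#' @param pairs data.frame from [simulate_short_pairs()].
#' @param r1,r2 output paths.
#' @return invisibly, `c(r1, r2)`.
#' @export
write_pair_fastq <- function(pairs, r1, r2) {
  write_fastq(paste0(pairs$pair_id, "/1"), pairs$read1, r1)
  write_fastq(paste0(pairs$pair_id, "/2"), pairs$read2, r2)
  invisible(c(r1, r2))
}
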