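# -- small DNA utilities -------------------------------------------------------

.valid_dna <- function(x) grepl("^[ACGT]+$", x)

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' All rotations of a string
#'
#' @param x a single string.
#' @return character vector of the `nchar(x)` cyclic rotations (including `x`).
#' @export
rotations <- function(x) {
  n <- nchar(x)
  vapply(seq_len(n) - 1L,
         function(i) paste0(substr(x, i + 1L, n), substr(x, 1L, i)),
         character(1))
}

#' Canonical key of a repeat motif
#'
#' Strand- and phase-free motif identity: the lexicographically smallest string
#' among all rotations of the motif and all rotations of its reverse
#' complement.  Two motifs denote the same tandem repeat class iff their
#' canonical keys are equal (e.g. `TGTAT` and `TTGTA`; `TGAAA` and `TTTCA`).
#'
#' @param motif DNA string (uppercase A/C/G/T only).
#' @return the canonical key, a DNA string of the same length.
#' @examples
#' canonical_key("TGTAT") == canonical_key("TTGTA")
#' canonical_key("TGAAA") == canonical_key("TTTCA")
#' @export
.canon_cache <- new.env(parent = emptyenv())

canonical_key <- function(motif) {
  if (length(motif) != 1L || is.na(motif) || !nzchar(motif) || !.valid_dna(motif))
    stop("motif must be a non-empty string over A/C/G/T, got: ",
         deparse(motif), call. = FALSE)
  hit <- .canon_cache[[motif]]
  if (!is.null(hit)) return(hit)
  .canon_cache[[motif]] <- min(c(rotations(motif), rotations(revcomp(motif))))
}

# Rotation-only key (no reverse complement); used when scanning a single strand.
rotation_key <- function(motif) {
  if (!.valid_dna(motif)) stop("motif must be A/C/G/T only", call. = FALSE)
  min(rotations(motif))
}

# -- RepeatMotif ---------------------------------------------------------------

#' Construct a repeat motif
#'
#' A motif keeps its written ("display") orientation for reporting -- the
#' field names motifs as TTTCA, TTGTA etc., not as canonical rotations -- while
#' carrying a [canonical_key()] used for identity under rotation and reverse
#' complement.
#'
#' @param display DNA string, length 1-30, uppercase A/C/G/T.
#' @return an object of class `repeat_motif` with fields `display`,
#'   `canonical_key` and `length`.
#' @export
repeat_motif <- function(display) {
  if (length(display) != 1L || !.valid_dna(display))
    stop("motif must be a single A/C/G/T string, got: ", deparse(display),
         call. = FALSE)
  if (nchar(display) > 30L)
    stop("motif longer than 30 bp: ", display, call. = FALSE)
  structure(list(display = display,
                 canonical_key = canonical_key(display),
                 length = nchar(display)),
            class = "repeat_motif")
}

#' @export
print.repeat_motif <- function(x, ...) {
  cat(sprintf("<repeat_motif> %s (%d bp, canonical %s)\n",
              x$display, x$length, x$canonical_key))
  invisible(x)
}

#' Coerce to a list of repeat motifs
#'
#' @param motifs a character vector of motif strings, a single `repeat_motif`,
#'   or a list of `repeat_motif` objects.
#' @return list of `repeat_motif`, pairwise distinct by canonical key.
#' @export
as_motif_list <- function(motifs) {
  if (inherits(motifs, "repeat_motif")) motifs <- list(motifs)
  if (is.character(motifs)) motifs <- lapply(motifs, repeat_motif)
  if (!is.list(motifs) || length(motifs) == 0L)
    stop("motif list must be non-empty", call. = FALSE)
  motifs <- lapply(motifs, function(m)
    if (inherits(m, "repeat_motif")) m else repeat_motif(m))
  keys <- vapply(motifs, `[[`, character(1), "canonical_key")
  if (anyDuplicated(keys))
    stop("motifs must be pairwise distinct by canonical key; duplicated: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "), call. = FALSE)
  motifs
}

# -- regions and loci ----------------------------------------------------------

#' Parse a genomic region string
#'
#' User-facing region strings are 1-based inclusive, as printed in genome
#' browsers (`"chr5:10356339-10356411"`); internally coordinates are 0-based
#' half-open.
#'
#' @param region string `"contig:first-last"` with `first <= last`.
#' @return list with `contig`, `start` (0-based inclusive), `end` (exclusive).
#' @examples
#' parse_region("chr5:10356339-10356411")  # span 73 bp
#' @export
parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:[:space:]]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L)
    stop("malformed region string (expected contig:first-last): ",
         deparse(region), call. = FALSE)
  first <- as.numeric(m[3]); last <- as.numeric(m[4])
  if (first < 1 || first > last)
    stop("invalid region interval (need 1 <= first <= last): ", region,
         call. = FALSE)
  list(contig = m[2], start = first - 1, end = last)
}

#' Define a repeat locus
#'
#' @param name locus name, e.g. `"FAME3"`.
#' @param region region string (see [parse_region()]).
#' @param motifs target motifs (see [as_motif_list()]).
#' @return object of class `locus_spec`.
#' @export
locus_spec <- function(name, region, motifs) {
  r <- parse_region(region)
  structure(list(name = name, contig = r$contig, start = r$start, end = r$end,
                 target_motifs = as_motif_list(motifs)),
            class = "locus_spec")
}

#' The FAME3 pentanucleotide repeat locus
#'
#' Convenience constructor for the intronic *MARCHF6* repeat locus
#' (chr5:10356339-10356411 on hg38) with the motifs relevant to complex FAME
#' expansions: TTTTA (reference / benign), TTTCA (pathogenic), TTGTA (novel
#' expansion motif) and TTCCA (reverse-strand basecall artifact).
#'
#' @param composite also include the 15 bp composite motif TTTTATTTTATTTCA.
#' @return a `locus_spec`.
#' @export
fame3_locus <- function(composite = FALSE) {
  motifs <- c("TTTTA", "TTTCA", "TTGTA", "TTCCA")
  if (composite) motifs <- c(motifs, "TTTTATTTTATTTCA")
  locus_spec("FAME3", "chr5:10356339-10356411", motifs)
}

#' Read / write a locus definition as JSON
#'
#' JSON schema: `{name, region: "contig:first-last", motifs: ["TTTTA", ...]}`.
#'
#' @param path file path.
#' @return for the reader, a `locus_spec`.
#' @export
read_locus_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$name) || is.null(x$region) || is.null(x$motifs))
    stop("locus JSON must have fields name, region, motifs", call. = FALSE)
  locus_spec(x$name, x$region, x$motifs)
}

#' @rdname read_locus_json
#' @param locus a `locus_spec`.
#' @export
write_locus_json <- function(locus, path) {
  stopifnot(inherits(locus, "locus_spec"))
  region <- sprintf("%s:%d-%d", locus$contig, locus$start + 1L, locus$end)
  jsonlite::write_json(
    list(name = locus$name, region = region,
         motifs = vapply(locus$target_motifs, `[[`, character(1), "display")),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# -- repeat configurations -----------------------------------------------------

#' Construct a repeat configuration
#'
#' An ordered list of (motif, copy-count) blocks with optional flanking
#' sequence; the in-memory form of structure strings such as
#' `"(TTTTA)100-(TTTCA)100-(TTTTA)100-(TTGTA)700"`.
#'
#' @param blocks data.frame with columns `motif` (character) and `copies`
#'   (positive integer).
#' @param left_flank,right_flank DNA strings (may be empty).
#' @return object of class `repeat_config`.
#' @export
repeat_config <- function(blocks, left_flank = "", right_flank = "") {
  stopifnot(is.data.frame(blocks), all(c("motif", "copies") %in% names(blocks)))
  if (nrow(blocks) > 0) {
    if (any(blocks$copies < 1 | blocks$copies != round(blocks$copies)))
      stop("block copy counts must be positive integers", call. = FALSE)
    keys <- vapply(blocks$motif, canonical_key, character(1))
    if (nrow(blocks) > 1 && any(keys[-1] == keys[-length(keys)]))
      stop("adjacent blocks must have distinct canonical keys", call. = FALSE)
  }
  if ((nzchar(left_flank) && !.valid_dna(left_flank)) ||
      (nzchar(right_flank) && !.valid_dna(right_flank)))
    stop("flanks must be A/C/G/T strings", call. = FALSE)
  blocks$copies <- as.integer(blocks$copies)
  blocks$bp <- as.integer(blocks$copies * nchar(blocks$motif))
  structure(list(blocks = blocks, left_flank = left_flank,
                 right_flank = right_flank),
            class = "repeat_config")
}

#' Parse a repeat configuration string
#'
#' Parses the `"(MOTIF)N-(MOTIF)N-..."` dialect (numeric copy counts in place
#' of the field's `exp` subscript) into a [repeat_config()].
#'
#' @param text configuration string.
#' @param left_flank,right_flank optional flanking DNA.
#' @return a `repeat_config`; round-trips through [format_config()].
#' @examples
#' parse_config("(TTTTA)100-(TTTCA)100")
#' @export
parse_config <- function(text, left_flank = "", right_flank = "") {
  if (length(text) != 1L || is.na(text) ||
      !grepl("^\\([ACGT]+\\)[0-9]+(-\\([ACGT]+\\)[0-9]+)*$", text))
    stop("malformed configuration string: ", deparse(text), call. = FALSE)
  m <- gregexpr("\\(([ACGT]+)\\)([0-9]+)", text)[[1]]
  parts <- regmatches(text, gregexpr("\\(([ACGT]+)\\)([0-9]+)", text))[[1]]
  motif <- sub("^\\(([ACGT]+)\\).*$", "\\1", parts)
  copies <- as.integer(sub("^\\([ACGT]+\\)([0-9]+)$", "\\1", parts))
  if (any(copies < 1L))
    stop("copy counts must be positive: ", text, call. = FALSE)
  repeat_config(data.frame(motif = motif, copies = copies),
                left_flank = left_flank, right_flank = right_flank)
}

#' Format a repeat configuration as a structure string
#'
#' @param config a `repeat_config`, or a data.frame of blocks.
#' @return string `"(MOTIF)N-..."`; `""` for an empty block list.
#' @export
format_config <- function(config) {
  blocks <- if (inherits(config, "repeat_config")) config$blocks else config
  if (nrow(blocks) == 0L) return("")
  paste(sprintf("(%s)%d", blocks$motif, blocks$copies), collapse = "-")
}

#' @export
print.repeat_config <- function(x, ...) {
  cat(sprintf("<repeat_config> %s\n", format_config(x)))
  cat(sprintf("  repeat: %d bp; flanks: %d + %d bp\n",
              sum(x$blocks$bp), nchar(x$left_flank), nchar(x$right_flank)))
  invisible(x)
}

#' Synthesize the DNA sequence of a repeat configuration
#'
#' Inverse of segmentation: concatenates `left_flank`, each block's motif
#' repeated `copies` times in order, then `right_flank`.
#'
#' @param config a `repeat_config`.
#' @return DNA string of length
#'   `nchar(left_flank) + sum(copies * motif length) + nchar(right_flank)`.
#' @export
config_to_sequence <- function(config) {
  stopifnot(inherits(config, "repeat_config"))
  b <- config$blocks
  body <- if (nrow(b) == 0L) "" else
    paste(strrep(b$motif, b$copies), collapse = "")
  paste0(config$left_flank, body, config$right_flank)
}

# total repeat bp of a configuration (closed form)
config_repeat_bp <- function(config) sum(config$blocks$bp)
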