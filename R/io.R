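# TSV interchange with provenance headers.  Every output file begins with
# '#'-prefixed comment lines (tool version, serialized configuration, config
# hash) so any result can be regenerated; no timestamps, so identical runs
# are byte-identical.

# short deterministic hash of the config JSON; base R only (no digest
# dependency) -- a polynomial rolling hash mod 2^31-1, for provenance ids,
# not cryptography
config_hash <- function(x) {
  h <- 0
  for (b in as.integer(charToRaw(x))) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

prov_header <- function(config = NULL) {
  ver <- as.character(utils::packageVersion("pentaplex"))
  lines <- sprintf("# pentaplex %s", ver)
  if (!is.null(config)) {
    js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
    lines <- c(lines, paste0("# config: ", js),
               paste0("# config_hash: ", config_hash(as.character(js))))
  }
  lines
}

#' Write a table as TSV with a provenance comment header
#'
#' @param df data.frame.
#' @param path output path.
#' @param config optional run configuration (list), serialized as JSON into
#'   the header together with a short hash.
#' @return the path, invisibly.
#' @export
write_tsv_prov <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(prov_header(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a provenance-headed TSV
#'
#' @param path file path.
#' @return data.frame (comment lines skipped).
#' @export
read_tsv_prov <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
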