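# Plain-text interchange: tab-delimited variant tables, FASTA (60-column
# wrap), JSON reports and YAML/JSON run configuration.

#' Write a variant table as TSV
#'
#' Tab-delimited with a header row, no quoting, NA written as empty.
#'
#' @param variants Data frame.
#' @param path Output path.
#' @export
write_variant_table <- function(variants, path) {
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a variant table from TSV
#'
#' @param path TSV path with a header row.
#' @return Data frame; empty allele_freq fields become NA.
#' @export
read_variant_table <- function(path) {
  out <- tryCatch(
    read.delim(path, sep = "\t", stringsAsFactors = FALSE, na.strings = ""),
    error = function(e) stop(sprintf("cannot parse '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE))
  out
}

#' Write sequences as FASTA (60-column wrap)
#'
#' @param seqs A [Biostrings::AAStringSet].
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA path.
#' @return A [Biostrings::AAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readAAStringSet(path)

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a run configuration from YAML or JSON
#'
#' The file mirrors the arguments of [run_config()]; nested `generator`
#' fields mirror [generator_config()] and `protocol` fields mirror
#' [split_protocol()].
#'
#' @param path Path ending in .yaml/.yml or .json.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop(sprintf("unsupported config extension '.%s'", ext), call. = FALSE)
  gen <- do.call(generator_config, c(raw$generator %||% list()))
  prot <- do.call(split_protocol, c(raw$protocol %||% list()))
  args <- raw[setdiff(names(raw), c("generator", "protocol"))]
  do.call(run_config, c(list(generator = gen, protocol = prot), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
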