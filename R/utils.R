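# Internal helpers shared across modules.

# Structured errors: every user-facing failure carries a machine-readable
# condition class (EMPTY_INPUT, SCHEMA, NO_DATA, INVALID_CDS, DOMAIN,
# SATURATED) so callers and the pipeline can dispatch on it.
cub_stop <- function(code, msg, call. = FALSE) {
  stop(errorCondition(sprintf("[%s] %s", code, msg),
                      class = c(code, "cubphylo_error")))
}

is_missing_num <- function(x) is.na(x)

#' Sentinel used for undefined numeric results
#'
#' Undefined quantities (Nc of a gene with too few synonymous families, deltas
#' for an absent housekeeping gene, the sample SD of a single value) are
#' carried as `NA_real_` in R objects and serialized as the literal string
#' `"MISSING"` in the package's TSV outputs (see [write_cub_tsv()]).
#' @keywords internal
#' @name missing-sentinel
NULL

MISSING_TOKEN <- "MISSING"

#' Write/read a TSV with explicit MISSING sentinels
#'
#' Thin wrappers around [utils::write.table()] / [utils::read.delim()] that
#' map `NA` to the literal token `MISSING` and back, so every table the
#' pipeline emits is re-parseable by the package itself.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_cub_tsv` returns a data.frame.
#' @export
write_cub_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = MISSING_TOKEN)
  invisible(path)
}

#' @rdname write_cub_tsv
#' @export
read_cub_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", na.strings = MISSING_TOKEN,
                    check.names = FALSE, stringsAsFactors = FALSE)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# stderr logging used by the validation and pipeline layers
cub_log <- function(fmt, ...) {
  message(sprintf(fmt, ...))
}
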