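#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and tests) can distinguish malformed files
# from data that parse but violate a type invariant.
abort_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("targettriage_format_error", "error")))
}

abort_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("targettriage_validation_error", "error")))
}

abort_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("targettriage_domain_error", "error")))
}

#' Canonicalize gene symbols
#'
#' Uppercases and trims whitespace. The uppercase symbol string is the join
#' key used across every module; canonicalization is idempotent.
#'
#' @param x character vector of symbols.
#' @return character vector of canonical symbols.
#' @export
canonical_symbol <- function(x) {
  toupper(trimws(as.character(x)))
}

# Comma-join a character vector for TSV serialization ("" for empty).
collapse_genes <- function(x) {
  vapply(x, function(g) paste(g, collapse = ","), character(1))
}

split_genes <- function(x) {
  lapply(x, function(s) if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ",", fixed = TRUE)[[1]])
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_domain(name, " must be a single finite number")
  }
}
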