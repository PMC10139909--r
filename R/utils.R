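# Small shared helpers. All text normalization in the package funnels
# through normalize_ws() so that raw_text, fragment text and manifests are
# comparable byte-for-byte.

#' Collapse runs of whitespace to single spaces and trim
#' @param x character vector
#' @return character vector of the same length
#' @keywords internal
normalize_ws <- function(x) {
  stringi::stri_trim_both(stringi::stri_replace_all_regex(x, "\\s+", " "))
}

#' Is `x` a plausible PMID digit string (1-8 decimal digits)?
#' @keywords internal
is_pmid_string <- function(x) {
  !is.na(x) & stringi::stri_detect_regex(x, "^[0-9]{1,8}$")
}

## package-level warning helper: consistent prefix, suppressible in bulk runs
cite_warn <- function(...) {
  warning(paste0(...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## NA-safe scalar character: NULL / empty / NA -> NA_character_
chr1 <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x[1])) NA_character_ else as.character(x[1])
}
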