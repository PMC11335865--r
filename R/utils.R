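`%||%` <- function(a, b) if (is.null(a)) b else a

# numeric coercion that never warns: unparseable -> NA
quiet_num <- function(x) suppressWarnings(as.numeric(x))

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

GENDER_LEVELS <- c("woman", "man")

#' Normalise free-form gender labels
#'
#' Maps common spellings ("woman", "female", "f", ...) onto the two-level
#' factor used throughout the package; anything unrecognised becomes `NA`.
#'
#' @param x character vector of raw gender labels.
#' @return factor with levels `c("woman", "man")`.
#' @keywords internal
normalize_gender <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("woman", "female", "f", "w")] <- "woman"
  out[x %in% c("man", "male", "m")] <- "man"
  factor(out, levels = GENDER_LEVELS)
}
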