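# Shared helpers: text normalisation, display rounding, percentage formatting.

# One calendar month is taken as 30.44 days throughout the package so that
# month-denominated onset parameters convert to days unambiguously.
DAYS_PER_MONTH <- 30.44

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.005 -> 0.01), the convention used
#' for displayed currency amounts and percentages.  Base `round()` rounds
#' half to even, which disagrees with printed financial tables.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(2.675, 2) # 2.68, where round() gives 2.67
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  z <- abs(x) * p
  # nudge compensates binary representation of values like 567.385
  sign(x) * floor(z + 0.5 + z * 1e-12) / p
}

#' Percentage of a count over a denominator
#'
#' @param n Numerator count(s).
#' @param d Denominator(s); must be positive.
#' @param digits Decimal places displayed (half-up rounding).
#' @return `100 * n / d` rounded to `digits` places.
#' @examples
#' pct(85, 1565) # 5.43
#' @export
pct <- function(n, d, digits = 2) {
  stopifnot(all(d > 0))
  round_half_up(100 * n / d, digits)
}

#' Normalise clinical free text for phrase matching
#'
#' Lower-cases, replaces every non-alphanumeric character run with a single
#' space and trims.  Matching downstream is plain substring search over this
#' normalised form, which makes phrase lookup case-insensitive and tolerant
#' of punctuation ("ground-glass" matches "ground glass") without imposing
#' word boundaries.
#'
#' @param x Character vector (NA treated as empty).
#' @return Normalised character vector.
#' @export
normalise_text <- function(x) {
  x[is.na(x)] <- ""
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(x)
}

# any normalised phrase occurs in normalised text? vectorised over text
phrase_hits <- function(text_norm, phrases_norm) {
  hits <- matrix(FALSE, nrow = length(text_norm), ncol = length(phrases_norm),
                 dimnames = list(NULL, phrases_norm))
  for (j in seq_along(phrases_norm)) {
    hits[, j] <- grepl(phrases_norm[j], text_norm, fixed = TRUE)
  }
  hits
}

# collapse a logical hit matrix into comma-separated matched phrase strings
collapse_hits <- function(hits) {
  if (nrow(hits) == 0) return(character(0))
  apply(hits, 1L, function(r) paste(colnames(hits)[r], collapse = ","))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
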