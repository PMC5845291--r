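#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for rendered percentages, so that
#' e.g. 0.275 displays as 0.28 rather than banker's-rounded 0.27. A small
#' epsilon guards against binary representations of exact `.xx5` values.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(0.125, -0.125), 2)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Render a proportion as a percent value
#'
#' @param x proportion(s) in `[0, 1]` (values outside are allowed for
#'   differences).
#' @param digits decimal places of the percent rendering (default 2).
#' @return numeric percent value(s), rounded half-up.
#' @export
#' @examples
#' as_percent(601 / 830)
as_percent <- function(x, digits = 2) round_half_up(100 * x, digits)

format_percent <- function(x, digits = 2) {
  sprintf(paste0("%.", digits, "f%%"), as_percent(x, digits))
}

# Internal key for a (drug, ADR) pair; \x1f (unit separator) cannot occur in
# sane names so the mapping is injective.
pair_key <- function(drug_name, adr_name) {
  paste(drug_name, adr_name, sep = "\x1f")
}

# Valid drug classes of the reporting system.
DRUG_TYPES <- c("TCM", "western", "biological")
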