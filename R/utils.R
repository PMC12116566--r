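#' Round half away from zero
#'
#' Base R's `round()` rounds half to even ("banker's rounding"); published
#' summary tables in pharmacoepidemiology conventionally round half up, so
#' 96.745 prints as 96.75 rather than 96.74. Used for every percentage the
#' package reports.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(2164 / 2237 * 100) # 96.74
#' round_half_up(0.125, 2) # 0.13, where round() gives 0.12
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Percentage of a count over a total, rounded half-up to two decimals
#'
#' The exact convention used in descriptive characteristics tables: the
#' percentage is computed on the stratum total and printed to two decimals.
#'
#' @param n Numerator count(s).
#' @param total Denominator (stratum total).
#' @return Numeric percentage(s); 0 when `total` is 0.
#' @examples
#' pct(2164, 2237) # 96.74
#' pct(555, 725) # 76.55
#' @export
pct <- function(n, total) {
  r <- 100 * n / total
  r[!is.finite(r)] <- 0 # empty stratum
  round_half_up(r, 2)
}

# --- YYYYMMDD integer date helpers -----------------------------------------
#
# FAERS dates arrive as integers: 8 digits (YYYYMMDD), 6 (YYYYMM) or 4
# (YYYY). Full precision is required for time-to-onset arithmetic; partial
# dates are padded with 01 for deduplication ordering only.

# TRUE when x is an 8-digit integer encoding a real calendar day
is_valid_ymd <- function(x) {
  out <- !is.na(x) & x >= 10000101 & x <= 99991231
  d <- suppressWarnings(as.Date(sprintf("%08d", x), format = "%Y%m%d"))
  out & !is.na(d)
}

# TRUE for 6-digit YYYYMM with a real month, or 4-digit YYYY
is_partial_ymd <- function(x) {
  ok6 <- !is.na(x) & x >= 100001 & x <= 999912 & (x %% 100) >= 1 & (x %% 100) <= 12
  ok4 <- !is.na(x) & x >= 1000 & x <= 9999
  ok6 | ok4
}

#' Pad a FAERS date to a full YYYYMMDD integer for ordering
#'
#' Partial dates (YYYYMM, YYYY) are padded with 01; invalid values become
#' `NA`. The padded value is used only to order reports (deduplication);
#' onset arithmetic requires a full date, see [ymd_to_date()].
#'
#' @param x Integer vector of YYYYMMDD / YYYYMM / YYYY values.
#' @return Integer vector of full YYYYMMDD values, `NA` where unparseable.
#' @export
pad_ymd <- function(x) {
  out <- rep(NA_integer_, length(x))
  full <- is_valid_ymd(x)
  out[full] <- x[full]
  p <- !full & is_partial_ymd(x)
  out[p & !is.na(x) & x <= 9999] <- as.integer(x[p & !is.na(x) & x <= 9999] * 10000L + 101L)
  p6 <- p & !is.na(x) & x > 9999
  out[p6] <- as.integer(x[p6] * 100L + 1L)
  out
}

#' Convert a full-precision YYYYMMDD integer to a Date
#'
#' Returns `NA` for partial (YYYYMM, YYYY) or invalid dates: day-level
#' arithmetic such as time-to-onset must not use padded dates.
#'
#' @param x Integer vector of YYYYMMDD values.
#' @return A `Date` vector.
#' @export
ymd_to_date <- function(x) {
  d <- rep(as.Date(NA), length(x))
  ok <- is_valid_ymd(x)
  d[ok] <- as.Date(sprintf("%08d", x[ok]), format = "%Y%m%d")
  d
}

# Date -> YYYYMMDD integer
date_to_ymd <- function(d) {
  as.integer(format(d, "%Y%m%d"))
}
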