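# Shared helpers and code tables for the FAERS dialect.

# Outcome codes used in the OUTC table (OUTC_COD column).
OUTCOME_CODES <- c(
  DE = "Death",
  DS = "Disability",
  HO = "Hospitalization",
  LT = "Life-threatening",
  OT = "Other serious",
  CA = "Congenital anomaly",
  RI = "Required intervention"
)

# Reporter occupation codes used in the DEMO table (OCCP_COD column).
OCCP_CODES <- c(
  MD = "Physician",
  PH = "Pharmacist",
  OT = "Other health professional",
  HP = "Health professional",
  CN = "Consumer",
  LW = "Lawyer"
)

DRUG_ROLE_CODES <- c("PS", "SS", "I", "C")

#' Round half away from zero
#'
#' Commercial rounding (half away from zero) rather than the IEEE
#' round-half-even rule used by [round()].  This is the rounding convention
#' under which published spontaneous-report summary tables reproduce exactly
#' from their counts and denominators.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded to `digits` decimals.
#' @examples
#' round_half_away(c(7.25, -7.25), 1) # 7.3, -7.3
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a denominator, rounded for display
#'
#' @param count Numeric vector of counts.
#' @param denominator Single positive number.
#' @param digits Decimal places (default 1).
#' @return `100 * count / denominator`, rounded half away from zero.
#' @export
percent_of <- function(count, denominator, digits = 1) {
  stopifnot(length(denominator) == 1L, denominator > 0)
  round_half_away(100 * count / denominator, digits)
}

# TRUE where x is a non-missing, non-empty string.
nz <- function(x) !is.na(x) & nzchar(x)

# yyyymmdd integer -> Date
ymd_int_to_date <- function(x) as.Date(sprintf("%08d", x), format = "%Y%m%d")

# Date -> yyyymmdd integer
date_to_ymd_int <- function(d) as.integer(format(d, "%Y%m%d"))
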