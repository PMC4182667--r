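# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Add whole years to a date
#'
#' "One year after" means the same month and day in the target year; Feb 29 is
#' clamped to Feb 28 when the target year is not a leap year.
#'
#' @param d a `Date` vector.
#' @param n integer number of years (scalar).
#' @return a `Date` vector.
#' @export
add_years <- function(d, n) {
  lt <- as.POSIXlt(d)
  feb29 <- !is.na(lt$mon) & lt$mon == 1L & lt$mday == 29L
  lt$year <- lt$year + n
  lt$mday[feb29] <- 28L
  as.Date(lt)
}

# Lehmer (minstd) step on doubles; all quantities < 2^53 so arithmetic is exact.
MINSTD_M <- 2147483647

minstd_mix <- function(z, rounds = 4L) {
  z <- z %% MINSTD_M
  z[z == 0] <- 1
  for (i in seq_len(rounds)) z <- (z * 16807) %% MINSTD_M
  z
}

# Stable numeric hash of person identifiers into [0, 2^31 - 1).
id_hash <- function(id) {
  if (is.numeric(id)) return((abs(id) %% MINSTD_M) * 48271 %% MINSTD_M)
  s <- as.character(id)
  vapply(s, function(x) {
    h <- 0
    for (code in utf8ToInt(x)) h <- (h * 31 + code) %% MINSTD_M
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Deterministic per-person uniform draw independent of cohort order.
hash_uniform <- function(seed, id) {
  z <- (as.numeric(seed) %% 65536) * 32749 + id_hash(id)
  minstd_mix(z) / MINSTD_M
}

# Derive a child RNG seed (< 2^31) from a base seed and a stream index.
child_seed <- function(seed, stream) {
  as.integer(minstd_mix((as.numeric(seed) %% 65536) * 32749 + 9973 * stream + 1))
}

DAYS_PER_YEAR <- 365.25

#' Round percentages so they sum exactly to 100
#'
#' Largest-remainder rounding at the given number of decimals, used when
#' emitting report tables so every percentage row sums to 100.0.
#'
#' @param p numeric vector of percentages summing to ~100.
#' @param digits decimals to keep (default 1).
#' @return rounded vector summing to exactly 100 at `digits` decimals.
#' @export
round_percent_100 <- function(p, digits = 1) {
  if (length(p) == 0 || any(is.na(p))) return(round(p, digits))
  f <- 10^digits
  x <- p * f
  fl <- floor(x)
  short <- round(100 * f - sum(fl))
  rem <- x - fl
  add <- rep(0, length(p))
  if (short > 0) add[order(rem, decreasing = TRUE)[seq_len(short)]] <- 1
  (fl + add) / f
}

calendar_year_of <- function(dates) as.integer(format(dates, "%Y"))

# Banding helpers used by the stratified tables and the model covariates.
records_band <- function(n) {
  cut(n, breaks = c(-Inf, 0, 3, 8, 18, 49, Inf),
      labels = c("0", "1-3", "4-8", "9-18", "19-49", "50+"))
}

bmi_band <- function(bmi) {
  out <- cut(bmi, breaks = c(-Inf, 20, 26, Inf), right = FALSE,
             labels = c("low", "normal", "overweight"))
  out <- factor(out, levels = c(levels(out), "unknown"))
  out[is.na(bmi)] <- "unknown"
  out
}

age_band <- function(age) {
  cut(age, breaks = c(-Inf, 44, 54, 64, Inf),
      labels = c("35-44", "45-54", "55-64", "65-74"))
}

calendar_period <- function(year) {
  cut(year, breaks = c(-Inf, 2000, 2003, 2006, 2009, Inf),
      labels = c("1998-2000", "2001-2003", "2004-2006", "2007-2009", "2010+"))
}

# factor with an explicit "unknown" level replacing NA (for display tables).
with_unknown <- function(x) {
  x <- as.factor(x)
  if (!"unknown" %in% levels(x)) x <- factor(x, levels = c(levels(x), "unknown"))
  x[is.na(x)] <- "unknown"
  droplevels(x)
}
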