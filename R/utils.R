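# Date and small numeric helpers shared across modules.

year_start <- function(year) as.Date(sprintf("%d-01-01", year))
year_end <- function(year) as.Date(sprintf("%d-12-31", year))
days_in_year <- function(year) {
  as.integer(year_start(year + 1L) - year_start(year))
}

# Cumulative weekday count: g(d) = number of Mon-Fri days in (-Inf, d],
# anchored so differences give exact closed-form counts. Day 0 (1970-01-01)
# is a Thursday, so e = d + 3 makes e %% 7 == 0 a Monday.
weekday_cumcount <- function(d) {
  e <- as.numeric(d) + 3
  5 * (e %/% 7) + pmin(e %% 7 + 1, 5)
}

#' Count weekdays (Mon-Fri) between two dates, inclusive
#'
#' Closed-form, vectorised; returns 0 when `to < from`.
#'
#' @param from,to `Date` vectors (recycled).
#' @return Integer vector of weekday counts.
#' @export
count_weekdays <- function(from, to) {
  from <- as.Date(from); to <- as.Date(to)
  n <- weekday_cumcount(as.integer(to)) - weekday_cumcount(as.integer(from) - 1L)
  as.integer(pmax(0, ifelse(to < from, 0, n)))
}

# Exact law of the generated (truncated-normal, rounded) integer ages:
# support 18..99 with cell probabilities from the normal CDF, the end cells
# covering only half-width rounding intervals.
age_law <- function(config) {
  k <- 18:99
  lo <- pmax(k - 0.5, 18)
  hi <- pmin(k + 0.5, 99)
  pk <- stats::pnorm((hi - config$age_mean) / config$age_sd) -
    stats::pnorm((lo - config$age_mean) / config$age_sd)
  list(k = k, pk = pk / sum(pk))
}

# Round a vector of positive shares of `total` to cents such that the
# rounded values sum exactly to `total` (residual assigned to the largest
# share). `total` is assumed already rounded to cents.
split_to_cents <- function(total, weights) {
  if (length(weights) == 1L) return(total)
  raw <- total * weights / sum(weights)
  out <- round(raw, 2)
  resid <- round(total - sum(out), 2)
  i <- which.max(weights)
  out[i] <- round(out[i] + resid, 2)
  out
}
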