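#' Human Capital Approach cost of short-term-disability days
#'
#' Values lost work time as `days * hours_per_day * hourly_wage`, computed
#' in integer cents so the result is exact to the cent, additive in days
#' (`hca_cost(a + b) = hca_cost(a) + hca_cost(b)`) and homogeneous of degree
#' one in the wage.
#'
#' @param std_days nonnegative integer day counts (NA passes through).
#' @param wage a [wage_config()].
#' @return Dollar costs, exact to the cent.
#' @export
hca_cost <- function(std_days, wage) {
  if (!inherits(wage, "wage_config")) {
    stop("wage must be a wage_config object", call. = FALSE)
  }
  if (any(std_days < 0, na.rm = TRUE)) {
    stop("std_days must be nonnegative", call. = FALSE)
  }
  day_cents <- round(wage$hours_per_day * wage$hourly_wage * 100)
  std_days * day_cents / 100
}
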