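# Poisson incidence-rate-ratio models for annual utilization counts: one
# model per (comorbidity, outcome), adjusted for age, gender, region and
# psoriasis severity; the reference group is patients without the respective
# comorbidity. Exposure is constant (12 outcome-year months for everyone by
# the continuous-enrollment rule) so no offset is used.

outcome_column <- function(outcome) {
  switch(outcome,
         outpatient = "outpatient_visits",
         hospitalization = "hospitalizations",
         er = "er_visits",
         stop("unknown utilization outcome: ", outcome, call. = FALSE))
}

#' Adjusted incidence rate ratio for one comorbidity and outcome
#'
#' Fits `count ~ comorbidity + age + male + region + severity` by Poisson
#' regression (log link) and reports the exponentiated comorbidity
#' coefficient with a Wald 95% confidence interval
#' (`exp(beta +/- 1.96 * SE)`) and two-sided Wald p-value.
#'
#' @param cohort analysis cohort.
#' @param comorbidity comorbidity flag column (or `"any_comorbidity"`).
#' @param outcome one of `"outpatient"`, `"hospitalization"`, `"er"`.
#' @return A one-row `data.table`: `comorbidity`, `outcome`, `irr`,
#'   `ci_low`, `ci_high`, `p_value`, `n`.
#' @export
fit_irr_per_comorbidity <- function(cohort, comorbidity,
                                    outcome = c("outpatient", "hospitalization", "er")) {
  outcome <- match.arg(outcome)
  cohort <- as.data.table(cohort)
  z <- cohort[[comorbidity]]
  if (is.null(z)) stop("comorbidity term absent from cohort: ", comorbidity,
                       call. = FALSE)
  if (all(z == 0)) stop("no exposed patients for ", comorbidity, call. = FALSE)
  if (all(z == 1)) stop("no unexposed patients for ", comorbidity, call. = FALSE)
  x <- build_design(cohort, comorbidity)
  y <- cohort[[outcome_column(outcome)]]
  fit <- fit_glm(x, y, "poisson")
  b <- fit$coefficients[[comorbidity]]
  se <- sqrt(fit$covariance[comorbidity, comorbidity])
  data.table(comorbidity = comorbidity, outcome = outcome,
             irr = exp(b),
             ci_low = exp(b - 1.96 * se),
             ci_high = exp(b + 1.96 * se),
             p_value = 2 * stats::pnorm(-abs(b / se)),
             n = fit$n_obs)
}

#' Adjusted IRRs for every comorbidity and utilization outcome
#'
#' @param cohort analysis cohort.
#' @param comorbidities comorbidity columns to model (the ten study
#'   comorbidities plus the any-comorbidity indicator by default).
#' @param outcomes utilization outcomes to model.
#' @return A `data.table` with one row per comorbidity x outcome.
#' @export
fit_irr_all <- function(cohort,
                        comorbidities = c(comorbidity_names(), "any_comorbidity"),
                        outcomes = utilization_outcomes()) {
  rbindlist(lapply(comorbidities, function(j) {
    rbindlist(lapply(outcomes, function(o) {
      fit_irr_per_comorbidity(cohort, j, o)
    }))
  }))
}
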