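#' Canonical names of the ten study comorbidities
#'
#' The comorbidity panel tracked throughout the package: psoriatic arthritis,
#' cardiovascular disease, depression, anxiety, diabetes, hyperlipidemia,
#' hypertension, obesity, cerebrovascular disease and peripheral vascular
#' disease.
#'
#' @return Character vector of length 10.
#' @export
comorbidity_names <- function() {
  c("psoriatic_arthritis", "cardiovascular_disease", "depression", "anxiety",
    "diabetes", "hyperlipidemia", "hypertension", "obesity",
    "cerebrovascular_disease", "peripheral_vascular_disease")
}

utilization_outcomes <- function() c("outpatient", "hospitalization", "er")

region_levels <- function() {
  c("northeast", "north_central", "south", "west", "missing")
}

# Default parameter blocks. Marginal prevalences, rate ratios and cost ratios
# follow published values for a large US commercial-claims psoriasis cohort;
# base rates and dispersion are realistic claims-data choices (see the
# methods vignette).
default_prevalence <- function() {
  stats::setNames(
    c(0.0985, 0.1771, 0.0778, 0.0558, 0.1424,
      0.3353, 0.3433, 0.0488, 0.0376, 0.0360),
    comorbidity_names()
  )
}

default_log_rate_effects <- function() {
  irr <- rbind(
    outpatient      = c(1.30, 1.51, 1.34, 1.36, 1.37, 1.21, 1.31, 1.38, 1.41, 1.47),
    hospitalization = c(1.40, 2.60, 2.05, 1.82, 1.93, 1.09, 1.71, 2.17, 2.08, 2.38),
    er              = c(1.36, 2.34, 1.99, 2.15, 1.77, 1.16, 1.63, 1.89, 2.01, 1.95)
  )
  colnames(irr) <- comorbidity_names()
  log(t(irr))  # comorbidity x outcome
}

default_cost_log_effects <- function() {
  ratio <- c(
    psoriatic_arthritis         = 25035.9 / 13376.2,
    cardiovascular_disease      = 22287.1 / 12853.8,
    depression                  = 20270.7 / 14040.2,
    anxiety                     = 17569.3 / 14344.9,
    diabetes                    = 22052.1 / 13275.2,
    hyperlipidemia              = 16502.7 / 13527.3,
    hypertension                = 18465.9 / 12464.5,
    obesity                     = 20827.1 / 14201.2,
    cerebrovascular_disease     = 23410.0 / 14177.5,
    peripheral_vascular_disease = 24871.7 / 14138.2
  )
  log(ratio)
}

default_std_log_effects <- function() {
  ratio <- c(
    psoriatic_arthritis         = 1346.7 / 860.0,
    cardiovascular_disease      = 1635.0 / 828.2,
    depression                  = 2112.7 / 825.0,
    anxiety                     = 1344.2 / 881.8,
    diabetes                    = 1816.3 / 804.7,
    hyperlipidemia              = 1163.2 / 803.3,
    hypertension                = 1319.0 / 775.9,
    obesity                     = 2293.4 / 856.6,
    cerebrovascular_disease     = 2501.5 / 880.4,
    peripheral_vascular_disease = 1912.2 / 891.6
  )
  log(ratio)
}

default_covariate_effects <- function() {
  list(
    outpatient      = c(age = 0.005,  male = -0.15, severity = 0.35),
    hospitalization = c(age = 0.020,  male =  0.05, severity = 0.10),
    er              = c(age = -0.005, male =  0.05, severity = 0.05),
    cost            = c(age = 0.010,  male = -0.05, severity = 0.60),
    std             = c(age = 0.005,  male =  0.00, severity = 0.10)
  )
}

#' Simulation configuration for the synthetic claims generator
#'
#' Builds a validated configuration object. Defaults emulate a large US
#' commercial/Medicare-supplemental psoriasis claims cohort over a
#' two-calendar-year window: demographics and comorbidity prevalences match
#' the published cohort profile, utilization rate ratios and cost ratios per
#' comorbidity match the published adjusted estimates, and the remaining
#' knobs (base rates, gamma shape, disability-day law) are realistic
#' claims-data choices documented in the methods vignette.
#'
#' Age, the male indicator and the severity indicator enter every log-linear
#' predictor centred/coded so that `utilization_base_rates` and
#' `cost_mean_base` describe a mild, female patient of average age with no
#' comorbidity. Comorbidity flags are drawn independently unless
#' `comorbidity_correlation > 0`, in which case an exchangeable Gaussian
#' copula couples the latent scales while preserving the marginals.
#'
#' @param n_patients number of cohort-eligible patients to simulate.
#' @param seed integer seed (< 2^31 - 1000); all randomness is derived from
#'   it via fixed per-stage offsets so adding a stage does not perturb others.
#' @param baseline_year first calendar year of the window; outcomes are
#'   measured in `baseline_year + 1`.
#' @param age_mean,age_sd normal age law (years), truncated to `[18, 99]` and
#'   rounded to whole years.
#' @param male_fraction proportion male.
#' @param region_probs 4 probabilities (northeast, north_central, south,
#'   west) summing to 1, conditional on region being recorded.
#' @param region_missing_fraction proportion with missing region.
#' @param comorbidity_prevalence named proportions for the ten comorbidities.
#' @param severity_fraction proportion receiving systemic therapy or
#'   phototherapy in the baseline year (the moderate-to-severe proxy).
#' @param utilization_base_rates named mean annual counts (outpatient,
#'   hospitalization, er) at reference covariates.
#' @param utilization_log_rate_effects comorbidity x outcome matrix of log
#'   rate ratios.
#' @param covariate_effects list of per-outcome log effects for `age` (per
#'   year, centred at `age_mean`), `male` and `severity`; components
#'   `outpatient`, `hospitalization`, `er`, `cost`, `std`.
#' @param cost_positive_prob probability of any year-2 direct cost.
#' @param cost_positive_logit_effects optional named log-odds effects of each
#'   comorbidity on having any cost (default all zero).
#' @param cost_mean_base mean positive year-2 cost (dollars) at reference
#'   covariates.
#' @param cost_log_effects named log cost ratios per comorbidity.
#' @param cost_shape gamma shape of the positive cost part.
#' @param std_eligible_fraction proportion with short-term-disability (HPM)
#'   eligibility in the outcome year.
#' @param std_day_model list: `zero_prob` (probability of zero STD days given
#'   eligibility), `mean_days` (mean positive days at reference covariates),
#'   `shape` (gamma shape of the positive-day draw before rounding), and
#'   `log_effects` (named log day ratios per comorbidity). Days are capped at
#'   260 weekdays/year.
#' @param hmo_fraction proportion enrolled in an HMO plan (excluded from the
#'   cost-analysis sample downstream).
#' @param decoy_fraction fraction (of `n_patients`) of additional "decoy"
#'   patients, each violating exactly one inclusion rule, cycled over the
#'   five rules; decoys are labelled in the generator's truth table so the
#'   cohort filter can be tested exactly.
#' @param comorbidity_correlation exchangeable latent (Gaussian-copula)
#'   correlation between comorbidities, in `[0, 1)`; 0 disables the copula.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_patients = 5000L,
                       seed = 1L,
                       baseline_year = 2010L,
                       age_mean = 51.63,
                       age_sd = 14.59,
                       male_fraction = 0.5001,
                       region_probs = c(northeast = 10485, north_central = 16528,
                                        south = 20633, west = 8660) / 56306,
                       region_missing_fraction = 100 / 56406,
                       comorbidity_prevalence = default_prevalence(),
                       severity_fraction = 13698 / 56406,
                       utilization_base_rates = c(outpatient = 8, hospitalization = 0.08, er = 0.18),
                       utilization_log_rate_effects = default_log_rate_effects(),
                       covariate_effects = default_covariate_effects(),
                       cost_positive_prob = 0.95,
                       cost_positive_logit_effects = NULL,
                       cost_mean_base = 6800,
                       cost_log_effects = default_cost_log_effects(),
                       cost_shape = 0.5,
                       std_eligible_fraction = 5878 / 56406,
                       std_day_model = list(zero_prob = 0.75, mean_days = 6.7,
                                            shape = 1, log_effects = default_std_log_effects()),
                       hmo_fraction = 0.12,
                       decoy_fraction = 0.05,
                       comorbidity_correlation = 0) {
  if (is.null(cost_positive_logit_effects)) {
    cost_positive_logit_effects <- stats::setNames(
      numeric(length(names(comorbidity_prevalence))),
      names(comorbidity_prevalence)
    )
  }
  cfg <- list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    baseline_year = as.integer(baseline_year),
    age_mean = age_mean, age_sd = age_sd, male_fraction = male_fraction,
    region_probs = region_probs, region_missing_fraction = region_missing_fraction,
    comorbidity_prevalence = comorbidity_prevalence,
    severity_fraction = severity_fraction,
    utilization_base_rates = utilization_base_rates,
    utilization_log_rate_effects = utilization_log_rate_effects,
    covariate_effects = covariate_effects,
    cost_positive_prob = cost_positive_prob,
    cost_positive_logit_effects = cost_positive_logit_effects,
    cost_mean_base = cost_mean_base,
    cost_log_effects = cost_log_effects,
    cost_shape = cost_shape,
    std_eligible_fraction = std_eligible_fraction,
    std_day_model = std_day_model,
    hmo_fraction = hmo_fraction,
    decoy_fraction = decoy_fraction,
    comorbidity_correlation = comorbidity_correlation
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

config_error <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_prop <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    config_error(field, "must be a proportion in [0, 1]")
  }
}

#' Validate a simulation configuration
#'
#' Checks every invariant of [sim_config()]; errors name the offending field.
#'
#' @param config a `sim_config` object or plain list with the same fields.
#' @return The config, invisibly, if valid.
#' @export
validate_sim_config <- function(config) {
  if (!is.numeric(config$n_patients) || length(config$n_patients) != 1 ||
      is.na(config$n_patients) || config$n_patients < 1) {
    config_error("n_patients", "must be a positive integer")
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1 || is.na(config$seed)) {
    config_error("seed", "must be a single integer")
  }
  if (!is.numeric(config$age_sd) || config$age_sd <= 0) {
    config_error("age_sd", "must be > 0")
  }
  check_prop(config$male_fraction, "male_fraction")
  if (length(config$region_probs) != 4) {
    config_error("region_probs", "must have exactly 4 entries")
  }
  check_prop(config$region_probs, "region_probs")
  if (abs(sum(config$region_probs) - 1) > 1e-12) {
    config_error("region_probs", "must sum to 1 within 1e-12")
  }
  check_prop(config$region_missing_fraction, "region_missing_fraction")
  check_prop(config$comorbidity_prevalence, "comorbidity_prevalence")
  if (is.null(names(config$comorbidity_prevalence)) ||
      anyDuplicated(names(config$comorbidity_prevalence))) {
    config_error("comorbidity_prevalence", "must be uniquely named")
  }
  check_prop(config$severity_fraction, "severity_fraction")
  if (any(config$utilization_base_rates <= 0)) {
    config_error("utilization_base_rates", "must all be > 0")
  }
  if (!all(utilization_outcomes() %in% names(config$utilization_base_rates))) {
    config_error("utilization_base_rates",
                 "must name outpatient, hospitalization and er rates")
  }
  eff <- config$utilization_log_rate_effects
  if (!is.matrix(eff) ||
      !all(rownames(eff) %in% names(config$comorbidity_prevalence)) ||
      !all(utilization_outcomes() %in% colnames(eff))) {
    config_error("utilization_log_rate_effects",
                 "must be a comorbidity x outcome matrix matching the prevalence names")
  }
  check_prop(config$cost_positive_prob, "cost_positive_prob")
  if (!is.numeric(config$cost_mean_base) || config$cost_mean_base <= 0) {
    config_error("cost_mean_base", "must be > 0")
  }
  if (!all(names(config$comorbidity_prevalence) %in% names(config$cost_log_effects))) {
    config_error("cost_log_effects", "must be named for every comorbidity")
  }
  if (!is.numeric(config$cost_shape) || config$cost_shape <= 0) {
    config_error("cost_shape", "must be > 0")
  }
  check_prop(config$std_eligible_fraction, "std_eligible_fraction")
  sdm <- config$std_day_model
  if (!is.list(sdm) || is.null(sdm$zero_prob) || is.null(sdm$mean_days) ||
      is.null(sdm$shape)) {
    config_error("std_day_model", "must list zero_prob, mean_days and shape")
  }
  check_prop(sdm$zero_prob, "std_day_model$zero_prob")
  if (sdm$mean_days <= 0) config_error("std_day_model$mean_days", "must be > 0")
  if (sdm$shape <= 0) config_error("std_day_model$shape", "must be > 0")
  check_prop(config$hmo_fraction, "hmo_fraction")
  check_prop(config$decoy_fraction, "decoy_fraction")
  if (config$comorbidity_correlation < 0 || config$comorbidity_correlation >= 1) {
    config_error("comorbidity_correlation", "must be in [0, 1)")
  }
  for (nm in c("outpatient", "hospitalization", "er", "cost", "std")) {
    ce <- config$covariate_effects[[nm]]
    if (is.null(ce) || !all(c("age", "male", "severity") %in% names(ce))) {
      config_error("covariate_effects",
                   sprintf("component '%s' must name age, male and severity effects", nm))
    }
  }
  invisible(config)
}

# Per-stage sub-seed: one named stream, fixed offsets per table/stage, so
# adding a stage never perturbs the draws of another.
sub_seed <- function(seed, offset) {
  (abs(as.integer(seed)) %% 2147400000L) + as.integer(offset)
}
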