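#' Diagnosis code-set configuration
#'
#' Bundles the ICD-9-CM code sets used to identify psoriasis, the study
#' comorbidities (by code prefix), the severity proxy (systemic-therapy and
#' phototherapy claim markers), and the Charlson Comorbidity Index weight
#' map. The defaults are small, documented sets sufficient for synthetic
#' data and for exercising the matching logic; real analyses should supply
#' complete, clinically validated sets via this same structure (or a YAML
#' file with the same keys).
#'
#' Comorbidity matching is by prefix: a diagnosis string matches when any
#' configured prefix is a leading substring of it, so `"250"` matches
#' `"250.00"`.
#'
#' @param psoriasis_codes exact ICD-9-CM codes defining a psoriasis claim.
#' @param comorbidity_codes named list of prefix sets, one per comorbidity.
#' @param systemic_therapy_markers,phototherapy_markers claim markers (codes
#'   carried in the dx fields) defining moderate-to-severe psoriasis when
#'   seen in the baseline year.
#' @param cci_weights named list of Charlson conditions, each
#'   `list(weight = integer, codes = prefix set)`.
#'
#' @return An object of class `code_config`.
#' @export
code_config <- function(psoriasis_codes = c("696.1", "696.8"),
                        comorbidity_codes = default_comorbidity_codes(),
                        systemic_therapy_markers = c("RX_METHOTREXATE", "RX_ACITRETIN",
                                                     "RX_CYCLOSPORINE", "RX_BIOLOGIC"),
                        phototherapy_markers = c("PROC_96910", "PROC_96912"),
                        cci_weights = default_cci_weights()) {
  if (length(psoriasis_codes) == 0) {
    config_error("psoriasis_codes", "must be non-empty")
  }
  structure(
    list(psoriasis_codes = psoriasis_codes,
         comorbidity_codes = comorbidity_codes,
         systemic_therapy_markers = systemic_therapy_markers,
         phototherapy_markers = phototherapy_markers,
         cci_weights = cci_weights),
    class = "code_config"
  )
}

#' @rdname code_config
#' @export
default_comorbidity_codes <- function() {
  list(
    psoriatic_arthritis         = c("696.0"),
    cardiovascular_disease      = c("410", "411", "412", "413", "414", "428"),
    depression                  = c("296.2", "296.3", "300.4", "311"),
    anxiety                     = c("300.0"),
    diabetes                    = c("250"),
    hyperlipidemia              = c("272.0", "272.1", "272.2", "272.4"),
    hypertension                = c("401", "402", "403", "404", "405"),
    obesity                     = c("278.0"),
    cerebrovascular_disease     = c("430", "431", "433", "434", "436", "438"),
    peripheral_vascular_disease = c("443", "440.2")
  )
}

#' @rdname code_config
#' @export
default_cci_weights <- function() {
  # Charlson/Deyo-style weights over a compact prefix map; overlapping with
  # the comorbidity sets on purpose so simulated comorbidity claims induce a
  # non-degenerate CCI distribution.
  list(
    myocardial_infarction   = list(weight = 1L, codes = c("410", "412")),
    congestive_heart_failure = list(weight = 1L, codes = c("428")),
    peripheral_vascular     = list(weight = 1L, codes = c("443", "440.2")),
    cerebrovascular         = list(weight = 1L, codes = c("430", "431", "433", "434", "436", "438")),
    diabetes                = list(weight = 1L, codes = c("250.0", "250.1", "250.2", "250.3")),
    diabetes_complications  = list(weight = 2L, codes = c("250.4", "250.5", "250.6")),
    renal_disease           = list(weight = 2L, codes = c("582", "585", "586")),
    liver_disease_mild      = list(weight = 1L, codes = c("571.2", "571.5", "571.6")),
    copd                    = list(weight = 1L, codes = c("490", "491", "492", "496")),
    malignancy              = list(weight = 2L, codes = c("140", "150", "160", "170", "180", "190"))
  )
}

#' Wage configuration for human-capital indirect-cost valuation
#'
#' The hourly wage has no package default: the intended value (e.g. the
#' BLS average hourly wage for all private industries in the outcome year)
#' must be supplied by the caller.
#'
#' @param hourly_wage average hourly wage in dollars; required, must be > 0.
#' @param hours_per_day working hours valued per disability day; in (0, 24].
#' @return An object of class `wage_config`.
#' @export
wage_config <- function(hourly_wage, hours_per_day = 8) {
  if (missing(hourly_wage) || !is.numeric(hourly_wage) ||
      length(hourly_wage) != 1 || is.na(hourly_wage) || hourly_wage <= 0) {
    config_error("hourly_wage", "is required and must be a single value > 0")
  }
  if (!is.numeric(hours_per_day) || hours_per_day <= 0 || hours_per_day > 24) {
    config_error("hours_per_day", "must be in (0, 24]")
  }
  structure(list(hourly_wage = hourly_wage, hours_per_day = hours_per_day),
            class = "wage_config")
}
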