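#' Published reference counts for a large US psoriasis claims cohort
#'
#' Summary counts from the published large US commercial/Medicare-
#' supplemental claims analysis of comorbidity burden in psoriasis
#' (2010-2011; N = 56,406 in the direct-cost sample, 5,878 in the
#' short-term-disability sample) that the synthetic generator's defaults
#' emulate. These counts are inputs for validation: the package's
#' descriptive statistics recompute the published percentages and bivariate
#' chi-square p-values from them at run time.
#'
#' @return A list: cohort sizes, per-comorbidity counts overall and by
#'   severity group, and sex counts by severity group.
#' @export
reference_counts <- function() {
  comorb <- data.table(
    comorbidity = comorbidity_names(),
    total   = c(5557L, 9992L, 4388L, 3148L, 8031L, 18911L, 19365L, 2755L, 2122L, 2032L),
    modsev  = c(2901L, 2390L, 1161L,  734L, 2181L,  4572L,  4775L,  709L,  462L,  457L),
    mild    = c(2656L, 7602L, 3227L, 2414L, 5850L, 14339L, 14590L, 2046L, 1660L, 1575L)
  )
  list(
    n_total = 56406L,
    n_moderate_severe = 13698L,
    n_mild = 42708L,
    n_indirect_sample = 5878L,
    male_total = 28208L,
    male_modsev = 6717L,
    male_mild = 21491L,
    any_comorbidity_total = 35644L,
    comorbidities = comorb
  )
}
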