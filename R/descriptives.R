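# Bivariate descriptive comparisons by psoriasis severity (the "Table 1"
# surface): counts/percentages with Pearson chi-square tests for categorical
# variables, means/SDs with Welch t-tests for continuous ones.

#' Pearson chi-square test on a 2x2 table
#'
#' Counts are laid out as exposure by group: `a` exposed in group 1, `b`
#' unexposed in group 1, `c` exposed in group 2, `d` unexposed in group 2.
#' No continuity correction is applied; the statistic equals the squared
#' two-proportion z statistic with pooled variance, df = 1.
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @return A list with `statistic`, `p_value`, `test = "chi_square"` and
#'   per-group `group_summaries` (n and proportion exposed).
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0)) {
    stop("cell counts must be nonnegative", call. = FALSE)
  }
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    stop("chi-square test undefined: a table margin is zero", call. = FALSE)
  }
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 / prod(margins)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       test = "chi_square",
       group_summaries = data.table(
         group = c(1L, 2L), n = c(a + b, c + d),
         proportion = c(a / (a + b), c / (c + d))))
}

#' Welch two-sample t-test from summary statistics
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return A list with `statistic` (t), `df`, `p_value`, `test = "t_test"`
#'   and `group_summaries`.
#' @export
t_test_two_sample <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (!is.finite(sd1) || !is.finite(sd2) || sd1 <= 0 || sd2 <= 0) {
    stop("group standard deviations must be > 0", call. = FALSE)
  }
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(statistic = t, df = df,
       p_value = 2 * stats::pt(-abs(t), df),
       test = "t_test",
       group_summaries = data.table(group = c(1L, 2L), n = c(n1, n2),
                                    mean = c(mean1, mean2), sd = c(sd1, sd2)))
}

sample_sd <- function(x) if (length(x) < 2) NA_real_ else stats::sd(x)

# Pearson chi-square over an r x c contingency table (no correction);
# NA when the test is undefined (zero margin or a degenerate dimension).
rxc_p_value <- function(tab) {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) || any(dim(tab) < 2)) {
    return(NA_real_)
  }
  suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
}

#' Summarize a cohort by psoriasis severity (Table-1 structure)
#'
#' For categorical variables: n and percentage overall and within each
#' severity group, with a Pearson chi-square p-value (2x2 via
#' [chi_square_2x2()], r x c via the general Pearson statistic). For
#' continuous variables: mean and sample SD (n - 1 denominator; NA for a
#' single observation) with a Welch t-test p-value.
#'
#' @param cohort an analysis cohort (see [build_cohort()]).
#' @param comorbidities comorbidity flag columns to tabulate.
#' @return A `data.table` with one row per variable/level: overall and
#'   per-severity-group summaries plus `p_value` and `test`.
#' @export
summarize_cohort <- function(cohort, comorbidities = comorbidity_names()) {
  cohort <- as.data.table(cohort)
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  validate_cohort(cohort, comorbidities)
  ms <- cohort$severity == "moderate_severe"
  n <- nrow(cohort)
  n_ms <- sum(ms)
  n_mild <- n - n_ms

  rows <- list()
  cont_row <- function(variable, x) {
    p <- tryCatch(
      t_test_two_sample(mean(x[ms]), sample_sd(x[ms]), n_ms,
                        mean(x[!ms]), sample_sd(x[!ms]), n_mild)$p_value,
      error = function(e) NA_real_)
    data.table(variable = variable, level = "", type = "continuous",
               overall_n = n, overall = mean(x), overall_sd = sample_sd(x),
               modsev_n = n_ms, modsev = if (n_ms) mean(x[ms]) else NA_real_,
               modsev_sd = sample_sd(x[ms]),
               mild_n = n_mild, mild = if (n_mild) mean(x[!ms]) else NA_real_,
               mild_sd = sample_sd(x[!ms]),
               p_value = p, test = "t_test")
  }
  binary_row <- function(variable, flag, level = "") {
    a <- sum(flag & ms); b1 <- n_ms - a
    c <- sum(flag & !ms); d <- n_mild - c
    p <- tryCatch(chi_square_2x2(a, b1, c, d)$p_value,
                  error = function(e) NA_real_)
    data.table(variable = variable, level = level, type = "categorical",
               overall_n = sum(flag), overall = 100 * sum(flag) / n,
               overall_sd = NA_real_,
               modsev_n = a, modsev = if (n_ms) 100 * a / n_ms else 0,
               modsev_sd = NA_real_,
               mild_n = c, mild = if (n_mild) 100 * c / n_mild else 0,
               mild_sd = NA_real_,
               p_value = p, test = "chi_square")
  }

  rows$age <- cont_row("age", cohort$age)
  male <- cohort$sex == "M"
  sex_rows <- rbind(binary_row("sex", male, "male"),
                    binary_row("sex", !male, "female"))
  sex_rows$p_value[2] <- NA_real_  # one test per variable
  rows$sex <- sex_rows

  reg <- factor(cohort$region, levels = region_levels())
  reg <- droplevels(reg)
  reg_p <- rxc_p_value(table(reg, ms))
  reg_rows <- rbindlist(lapply(levels(reg), function(lv) {
    binary_row("region", cohort$region == lv, lv)
  }))
  reg_rows[, p_value := c(reg_p, rep(NA_real_, .N - 1L))]
  reg_rows[, test := "chi_square"]
  rows$region <- reg_rows

  if ("cci" %in% names(cohort)) rows$cci <- cont_row("cci", cohort$cci)
  for (j in comorbidities) {
    rows[[j]] <- binary_row(j, cohort[[j]] == 1L)
  }
  rows$any <- binary_row("any_comorbidity", cohort$any_comorbidity == 1L)
  rbindlist(rows)
}

#' Display rounding helpers matching the report conventions
#'
#' Percentages are shown to 2 decimals, p-values to 4 decimals with values
#' below 0.00005 shown as `"<0.0001"`, and costs to 1 decimal.
#'
#' @param x numeric vector.
#' @return Character vector.
#' @export
format_pct <- function(x) sprintf("%.2f", x)

#' @rdname format_pct
#' @export
format_p <- function(x) {
  ifelse(is.na(x), "",
         ifelse(x < 0.00005, "<0.0001", sprintf("%.4f", x)))
}

#' @rdname format_pct
#' @export
format_cost <- function(x) sprintf("%.1f", x)
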