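test_that("the 2x2 chi-square equals the squared pooled two-proportion z statistic", {
  set.seed(42)
  for (i in 1:30) {
    a <- sample(1:500, 1); b <- sample(1:500, 1)
    c <- sample(1:500, 1); d <- sample(1:500, 1)
    res <- chi_square_2x2(a, b, c, d)
    p1 <- a / (a + b); p2 <- c / (c + d)
    pp <- (a + c) / (a + b + c + d)
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / (a + b) + 1 / (c + d)))
    expect_lt(abs(res$statistic - z^2), 1e-9)
    # label swap leaves the p-value unchanged
    expect_equal(chi_square_2x2(c, d, a, b)$p_value, res$p_value)
    # agrees with the stats engine
    expect_equal(res$p_value,
                 suppressWarnings(stats::chisq.test(matrix(c(a, c, b, d), 2),
                                                    correct = FALSE)$p.value),
                 tolerance = 1e-12)
  }
})

test_that("identical proportions give a zero statistic and p = 1", {
  res <- chi_square_2x2(50, 50, 500, 500)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("zero margins make the chi-square error", {
  expect_error(chi_square_2x2(0, 0, 5, 5), "margin")
  expect_error(chi_square_2x2(0, 5, 0, 5), "margin")
})

test_that("the Welch t-test matches a numeric t-density integration oracle", {
  res <- t_test_two_sample(1.3, 0.8, 14, 0.9, 1.1, 9)
  oracle <- 2 * stats::integrate(function(u) stats::dt(u, res$df),
                                 abs(res$statistic), Inf)$value
  expect_equal(res$p_value, oracle, tolerance = 1e-8)
  expect_equal(t_test_two_sample(2, 1, 30, 2, 1, 30)$p_value, 1)
  expect_lt(t_test_two_sample(0, 1, 10000, 1, 1, 10000)$p_value, 1e-10)
  expect_error(t_test_two_sample(1, 1, 1, 2, 1, 30), "n >= 2")
  expect_error(t_test_two_sample(1, 0, 10, 2, 1, 30), "standard deviations")
})

test_that("cohort summary percentages for exclusive categories sum to 100", {
  cfg <- tiny_config(n = 800, seed = 13)
  tb <- generate_population(cfg)
  co <- build_cohort(tb)$cohort
  t1 <- summarize_cohort(co)
  sex_pct <- t1[variable == "sex", overall]
  expect_lt(abs(sum(as.numeric(format_pct(sex_pct))) - 100), 0.05)
  reg_pct <- t1[variable == "region", overall]
  expect_lt(abs(sum(as.numeric(format_pct(reg_pct))) - 100), 0.05)
  # counts are consistent with the cohort
  expect_equal(t1[variable == "psoriatic_arthritis", overall_n],
               sum(co$psoriatic_arthritis))
  expect_equal(t1[variable == "age", overall], mean(co$age))
})

test_that("degenerate cohorts are summarized sensibly", {
  co <- toy_cohort(1)
  co[, `:=`(psoriatic_arthritis = 0L, cardiovascular_disease = 0L,
            depression = 0L, anxiety = 0L, diabetes = 0L, hyperlipidemia = 0L,
            hypertension = 0L, obesity = 0L, cerebrovascular_disease = 0L,
            peripheral_vascular_disease = 0L)]
  t1 <- summarize_cohort(co)
  expect_true(is.na(t1[variable == "age", overall_sd]))
  expect_error(summarize_cohort(co[0]), "empty")
  # all-mild cohort: the moderate-to-severe column is all zero
  co2 <- copy(toy_cohort(50))
  co2[, `:=`(severity = "mild", psoriatic_arthritis = flag,
             cardiovascular_disease = 0L, depression = 0L, anxiety = 0L,
             diabetes = 0L, hyperlipidemia = 0L, hypertension = 0L,
             obesity = 0L, cerebrovascular_disease = 0L,
             peripheral_vascular_disease = 0L)]
  t2 <- summarize_cohort(co2)
  expect_true(all(t2[type == "categorical", modsev_n] == 0))
})

test_that("display formatting follows the report conventions", {
  expect_equal(format_pct(9.8547), "9.85")
  expect_equal(format_p(c(0.00004, 0.0005, NA)), c("<0.0001", "0.0005", ""))
  expect_equal(format_cost(9914.33), "9914.3")
})
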