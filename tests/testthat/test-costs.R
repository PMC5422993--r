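test_that("intercept-only two-part expected cost is exactly p times the positive mean", {
  n <- 200
  co <- toy_cohort(n)
  y <- c(rep(0, n / 2), rgamma(n / 2, 2, rate = 2 / 1000))
  co[, direct_cost_total := y]
  fit <- fit_two_part(co, comorbidity = NULL, covariates = character())
  expect_equal(mean(expected_cost(fit)),
               0.5 * mean(y[y > 0]), tolerance = 1e-9)
})

test_that("scaling all costs by k shifts only the gamma intercept by log(k)", {
  co <- toy_cohort(800, seed = 3)
  f1 <- fit_two_part(co, "flag")
  co2 <- copy(co)
  co2[, direct_cost_total := direct_cost_total * 7]
  f2 <- fit_two_part(co2, "flag")
  expect_equal(f1$part1$coefficients, f2$part1$coefficients, tolerance = 1e-8)
  d <- f2$part2$coefficients - f1$part2$coefficients
  expect_equal(d[["(Intercept)"]], log(7), tolerance = 1e-7)
  expect_lt(max(abs(d[-1])), 1e-7)
  expect_equal(mean(expected_cost(f2)), 7 * mean(expected_cost(f1)),
               tolerance = 1e-7)
})

test_that("two-part fitting matches the independent likelihood oracle", {
  co <- toy_cohort(500, seed = 11)
  fit <- fit_two_part(co, "flag")
  x <- fit$design
  y <- co$direct_cost_total
  expect_lt(max(abs(fit$part1$coefficients -
                      oracle_glm(x, as.numeric(y > 0), "binomial"))), 1e-6)
  expect_lt(max(abs(fit$part2$coefficients -
                      oracle_glm(x[y > 0, ], y[y > 0], "gamma"))), 1e-6)
})

test_that("degenerate cost distributions direct the caller to a one-part model", {
  co <- toy_cohort(100)
  co[, direct_cost_total := abs(direct_cost_total) + 1]
  expect_error(fit_two_part(co, "flag"), "one-part")
  co[, direct_cost_total := 0]
  expect_error(fit_two_part(co, "flag"), "zero")
})

test_that("null comorbidity coefficients give an incremental cost of exactly zero", {
  co <- toy_cohort(400, seed = 2)
  fit <- fit_two_part(co, "flag")
  fit$part1$coefficients[["flag"]] <- 0
  fit$part2$coefficients[["flag"]] <- 0
  est <- recycled_prediction(fit)
  expect_identical(est$incremental, 0)
})

test_that("hand-built intercept-only parts reproduce the closed-form increment", {
  # P(positive) = 0.5 throughout; positive mean 1000 unexposed, x2 exposed
  x <- cbind("(Intercept)" = rep(1, 50), flag = rbinom(50, 1, 0.4))
  fit <- structure(list(
    part1 = list(coefficients = c("(Intercept)" = 0, flag = 0)),
    part2 = list(coefficients = c("(Intercept)" = log(1000), flag = log(2))),
    design = x, comorbidity = "flag", cost_col = "direct_cost_total"
  ), class = "two_part_fit")
  est <- recycled_prediction(fit)
  expect_equal(est$adjusted_cost_unexposed, 500, tolerance = 1e-12)
  expect_equal(est$adjusted_cost_exposed, 1000, tolerance = 1e-12)
  expect_equal(est$incremental, 500, tolerance = 1e-12)
  expect_error(recycled_prediction(fit, "absent"), "absent")
})

test_that("the incremental estimate is strictly increasing in the gamma-part coefficient", {
  co <- toy_cohort(400, seed = 4)
  fit <- fit_two_part(co, "flag")
  inc <- sapply(c(-0.2, 0, 0.2, 0.5, 0.9), function(b) {
    f <- fit
    f$part2$coefficients[["flag"]] <- b
    recycled_prediction(f)$incremental
  })
  expect_true(all(diff(inc) > 0))
})

test_that("recycled prediction at observed exposure reproduces the mean fitted cost", {
  co <- toy_cohort(600, seed = 6)
  fit <- fit_two_part(co, "flag")
  x_obs <- fit$design  # indicator already at the observed values
  expect_equal(mean(expected_cost(fit, x_obs)), mean(expected_cost(fit)),
               tolerance = 1e-12)
  # and the standardized means bracket it
  est <- recycled_prediction(fit)
  m <- mean(expected_cost(fit))
  expect_true(min(est$adjusted_cost_exposed, est$adjusted_cost_unexposed) <= m)
  expect_true(max(est$adjusted_cost_exposed, est$adjusted_cost_unexposed) >= m)
})

test_that("bootstrap CIs are deterministic, constant for constant estimators, and match normal theory for the mean", {
  co <- data.frame(x = rnorm(500))
  set.seed(99)
  co$x <- rnorm(500)
  ci_const <- bootstrap_ci(function(d) 3.25, co, B = 50, seed = 1)
  expect_equal(ci_const, c(3.25, 3.25))
  ci1 <- bootstrap_ci(function(d) mean(d$x), co, B = 2000, seed = 42)
  ci2 <- bootstrap_ci(function(d) mean(d$x), co, B = 2000, seed = 42)
  expect_identical(ci1, ci2)
  theory <- mean(co$x) + c(-1.96, 1.96) * sd(co$x) / sqrt(500)
  expect_lt(max(abs(ci1 - theory)), 0.02)
  expect_error(bootstrap_ci(function(d) mean(d$x), co, B = 1, seed = 1), "B must be")
})

test_that("bootstrap fails loudly when too many replicates fail", {
  co <- data.frame(x = rnorm(100))
  expect_error(
    suppressMessages(bootstrap_ci(function(d) stop("boom"), co, B = 20, seed = 1)),
    "unstable")
})

test_that("incremental_cost recovers a known effect and is seed-deterministic", {
  cfg <- tiny_config(n = 4000, seed = 19)
  co <- simulate_cohort(cfg)
  a <- incremental_cost(co, "hypertension", B = 60, seed = 7)
  b <- incremental_cost(co, "hypertension", B = 60, seed = 7)
  expect_identical(a, b)
  expect_equal(a$incremental, a$adjusted_with - a$adjusted_without,
               tolerance = 1e-6)
  expect_lte(a$ci_low, a$ci_high)
  tr <- true_incremental_cost(cfg, "hypertension")
  # generous sanity band: right order of magnitude and sign
  expect_gt(a$incremental, 0)
  expect_lt(abs(a$incremental - tr$incremental), 0.6 * tr$incremental)
})

test_that("the closed-form truth responds correctly to its drivers", {
  cfg <- tiny_config()
  tr <- true_incremental_cost(cfg, "cardiovascular_disease")
  expect_equal(tr$incremental,
               tr$adjusted_cost_exposed - tr$adjusted_cost_unexposed)
  # doubling the base cost doubles the increment (log-link equivariance)
  cfg2 <- tiny_config(cost_mean_base = cfg$cost_mean_base * 2)
  tr2 <- true_incremental_cost(cfg2, "cardiovascular_disease")
  expect_equal(tr2$incremental, 2 * tr$incremental, tolerance = 1e-12)
  expect_error(true_incremental_cost(cfg, "not_a_comorbidity"), "unknown")
})
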