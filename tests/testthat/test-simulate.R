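test_that("a fixed seed reproduces identical tables; seeds differ otherwise", {
  cfg <- tiny_config(n = 300, seed = 77)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  for (tab in c("claims", "enrollment", "demographics", "disability", "truth")) {
    expect_identical(a[[tab]], b[[tab]], label = tab)
  }
  c2 <- generate_population(tiny_config(n = 300, seed = 78))
  expect_false(identical(a$claims, c2$claims))
})

test_that("comorbidity prevalence matches configuration within binomial error", {
  cfg <- sim_config(n_patients = 56406, seed = 12)
  co <- simulate_cohort(cfg)
  p <- cfg$comorbidity_prevalence[["psoriatic_arthritis"]]
  tol <- 3 * sqrt(p * (1 - p) / cfg$n_patients)
  expect_lt(abs(mean(co$psoriatic_arthritis) - p), tol)
  # all ten marginals inside 4-SE bands
  for (j in comorbidity_names()) {
    pj <- cfg$comorbidity_prevalence[[j]]
    expect_lt(abs(mean(co[[j]]) - pj), 4 * sqrt(pj * (1 - pj) / cfg$n_patients),
              label = j)
  }
})

test_that("zero prevalence gives no flags and base-rate utilization means", {
  cfg <- tiny_config(n = 20000, seed = 3,
                     comorbidity_prevalence = stats::setNames(rep(0, 10), comorbidity_names()),
                     severity_fraction = 0, male_fraction = 0)
  co <- simulate_cohort(cfg)
  expect_true(all(co$any_comorbidity == 0))
  for (j in comorbidity_names()) expect_true(all(co[[j]] == 0))
  # with no comorbidity/severity/male contributions the only variation is age
  law <- comorbidcost:::age_law(cfg)
  for (o in c("outpatient", "hospitalization", "er")) {
    b <- cfg$covariate_effects[[o]][["age"]]
    expected <- cfg$utilization_base_rates[[o]] *
      sum(law$pk * exp(b * (law$k - cfg$age_mean)))
    col <- switch(o, outpatient = "outpatient_visits",
                  hospitalization = "hospitalizations", er = "er_visits")
    se <- sqrt(stats::var(co[[col]]) / nrow(co))
    expect_lt(abs(mean(co[[col]]) - expected), 4 * se, label = o)
  }
})

test_that("sample age mean matches the truncated age law at large n", {
  cfg <- sim_config(n_patients = 50000, seed = 9)
  co <- simulate_cohort(cfg)
  law <- comorbidcost:::age_law(cfg)
  true_mean <- sum(law$k * law$pk)
  expect_lt(abs(mean(co$age) - true_mean), 3 * cfg$age_sd / sqrt(cfg$n_patients))
  expect_true(all(co$age >= 18 & co$age <= 99))
})

test_that("positive costs are strictly positive and zero-cost patients have no paid lines", {
  cfg <- tiny_config(n = 500, seed = 21)
  tb <- generate_population(cfg)
  tr <- tb$truth[is.na(decoy_rule)]
  expect_true(all(tr$direct_cost_total[tr$direct_cost_total > 0] >= 0.01))
  zero_ids <- tr[direct_cost_total == 0, patient_id]
  y2 <- tb$claims[patient_id %in% zero_ids &
                    service_date >= as.Date("2011-01-01")]
  expect_true(all(y2$paid_usd == 0))
  # per-claim lines sum back to the simulated annual total
  pos <- tb$claims[service_date >= as.Date("2011-01-01"),
                   .(s = round(sum(paid_usd), 2)), by = patient_id]
  m <- merge(pos, tr[, .(patient_id, direct_cost_total)], by = "patient_id")
  expect_true(all(abs(m$s - m$direct_cost_total) < 0.005))
})

test_that("generated claim dates stay inside the two-year window", {
  tb <- generate_population(tiny_config(n = 200, seed = 4))
  expect_true(all(tb$claims$service_date >= as.Date("2010-01-01")))
  expect_true(all(tb$claims$service_date <= as.Date("2011-12-31")))
  expect_true(all(tb$claims$patient_id %in% tb$demographics$patient_id))
  expect_true(all(tb$disability$patient_id %in% tb$demographics$patient_id))
})

test_that("decoy patients are labelled with the rule they violate", {
  cfg <- tiny_config(n = 200, seed = 31, decoy_fraction = 0.1)
  tb <- generate_population(cfg)
  dec <- tb$truth[!is.na(decoy_rule)]
  expect_equal(nrow(dec), 20)
  expect_true(all(dec$decoy_rule %in% inclusion_rules()))
  expect_setequal(unique(dec$decoy_variant),
                  c("age_under_18", "single_dx", "same_date_dx",
                    "no_baseline_dx", "enrollment_gap"))
})

test_that("the copula correlation knob couples flags while keeping marginals", {
  cfg0 <- tiny_config(n = 30000, seed = 15)
  cfg1 <- tiny_config(n = 30000, seed = 15, comorbidity_correlation = 0.5)
  z0 <- simulate_cohort(cfg0)
  z1 <- simulate_cohort(cfg1)
  r0 <- cor(z0$hypertension, z0$hyperlipidemia)
  r1 <- cor(z1$hypertension, z1$hyperlipidemia)
  expect_lt(abs(r0), 0.02)
  expect_gt(r1, 0.15)
  p <- cfg1$comorbidity_prevalence[["hypertension"]]
  expect_lt(abs(mean(z1$hypertension) - p), 4 * sqrt(p * (1 - p) / 30000))
})

test_that("write/read round-trips tables losslessly", {
  dir <- withr::local_tempdir()
  tb <- generate_population(tiny_config(n = 150, seed = 8))
  write_tables(tb, dir)
  back <- read_tables(dir)
  for (tab in c("claims", "enrollment", "demographics", "disability")) {
    expect_equal(as.data.frame(back[[tab]]), as.data.frame(tb[[tab]]),
                 label = tab)
  }
})

test_that("empty tables write header-only files that read back empty", {
  dir <- withr::local_tempdir()
  write_tables(raw_tables(), dir)
  for (f in c("claims.csv", "enrollment.csv", "demographics.csv", "disability.csv")) {
    lines <- readLines(file.path(dir, f))
    expect_length(lines, 1)
  }
  back <- read_tables(dir)
  expect_equal(nrow(back$claims), 0)
  expect_equal(nrow(back$disability), 0)
})

test_that("handcrafted fixture output is byte-stable and matches the golden files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  gt <- golden_tables()
  write_tables(gt, d1)
  write_tables(gt, d2)
  golden_dir <- system.file("extdata", "golden", package = "comorbidcost")
  for (f in c("claims.csv", "enrollment.csv", "demographics.csv", "disability.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(golden_dir, f)),
                     label = paste("golden", f))
  }
})
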