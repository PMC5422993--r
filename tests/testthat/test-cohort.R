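test_that("the inclusion cascade keeps the six valid handcrafted patients", {
  tb <- handcrafted_tables()
  inc <- apply_inclusion(tb, code_config())
  expect_setequal(inc$cohort$patient_id, sprintf("G%02d", 1:6))
  led <- inc$exclusions
  expect_equal(led[patient_id == "B_age", rule], "age_under_18")
  expect_equal(led[patient_id == "B_samedate", rule], "insufficient_psoriasis_dx")
  expect_equal(led[patient_id == "B_nobase", rule], "no_baseline_dx")
  expect_equal(led[patient_id == "B_gap", rule], "not_continuously_enrolled")
})

test_that("inclusion is invariant to input row order", {
  tb <- handcrafted_tables()
  set.seed(1)
  tb2 <- raw_tables(
    claims = tb$claims[sample(nrow(tb$claims))],
    enrollment = tb$enrollment[sample(nrow(tb$enrollment))],
    demographics = tb$demographics[sample(nrow(tb$demographics))],
    disability = tb$disability
  )
  a <- apply_inclusion(tb, code_config())
  b <- apply_inclusion(tb2, code_config())
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$exclusions, b$exclusions)
})

test_that("claims for a patient missing from demographics raise a data-integrity error", {
  tb <- handcrafted_tables()
  tb$claims <- rbind(tb$claims, ps_claim("GHOST", "2010-04-04"))
  expect_error(apply_inclusion(tb, code_config()), "GHOST")
})

test_that("on generated data the included set equals the non-decoys and HMO flags propagate", {
  cfg <- tiny_config(n = 300, seed = 55, decoy_fraction = 0.1)
  tb <- generate_population(cfg)
  inc <- apply_inclusion(tb, code_config())
  expect_setequal(inc$cohort$patient_id, tb$truth[is.na(decoy_rule), patient_id])
  led <- merge(inc$exclusions, tb$truth[, .(patient_id, decoy_rule)],
               by = "patient_id")
  expect_true(all(led$rule == led$decoy_rule))
  hmo <- tb$truth[is.na(decoy_rule) & plan_type == "HMO", patient_id]
  expect_true(all(inc$cohort[patient_id %in% hmo, in_cost_sample] == 0L))
  expect_true(all(inc$cohort[!patient_id %in% hmo, in_cost_sample] == 1L))
})

test_that("severity is moderate-to-severe only with a baseline-year therapy marker", {
  codes <- code_config()
  cl <- rbind(
    ps_claim("p1", "2010-05-05", dx = "PROC_96910"),     # baseline phototherapy
    ps_claim("p2", "2011-05-05", dx = "RX_BIOLOGIC",     # therapy only in outcome year
             setting = "pharmacy"),
    ps_claim("p3", "2010-05-05")                          # no therapy claim at all
  )
  sev <- classify_severity(cl, codes, c("p1", "p2", "p3"))
  expect_equal(sev$severity, c("moderate_severe", "mild", "mild"))
})

test_that("comorbidity flags use baseline-year prefix matching only", {
  codes <- code_config()
  cl <- rbind(
    ps_claim("p1", "2010-03-01", dx = "696.0"),   # PsA
    ps_claim("p2", "2011-03-01", dx = "696.0"),   # outcome year only
    ps_claim("p3", "2010-03-01", dx = "250.42"),  # prefix match for diabetes
    ps_claim("p4", "2010-03-01", dx = "")         # no diagnoses
  )
  fl <- flag_comorbidities(cl, codes, c("p1", "p2", "p3", "p4"))
  expect_equal(fl$psoriatic_arthritis, c(1L, 0L, 0L, 0L))
  expect_equal(fl$diabetes, c(0L, 0L, 1L, 0L))
  expect_equal(fl$any_comorbidity, c(1L, 0L, 1L, 0L))
})

test_that("the Charlson score adds configured weights once per condition", {
  w <- default_cci_weights()
  cl <- rbind(
    ps_claim("p1", "2010-01-01", dx = "410.11"),  # MI, weight 1
    ps_claim("p1", "2010-02-01", dx = "410.71"),  # same condition again
    ps_claim("p1", "2010-03-01", dx = "428.0"),   # CHF, weight 1
    ps_claim("p2", "2010-01-01", dx = "585.6"),   # renal, weight 2
    ps_claim("p2", "2010-02-01", dx = "428.0"),
    ps_claim("p3", "2010-01-01", dx = "")
  )
  cci <- compute_cci(cl, w, c("p1", "p2", "p3"))
  expect_equal(cci$cci, c(2L, 3L, 0L))
})

test_that("adding a claim never decreases the Charlson score", {
  w <- default_cci_weights()
  base <- ps_claim("p1", "2010-01-01", dx = "410.11")
  s0 <- compute_cci(base, w, "p1")$cci
  extra_codes <- c("", "999.9", "428.0", "250.51", "140.0")
  for (cd in extra_codes) {
    s1 <- compute_cci(rbind(base, ps_claim("p1", "2010-06-01", dx = cd)),
                      w, "p1")$cci
    expect_gte(s1, s0)
  }
})

test_that("outcome derivation counts distinct dates and merges consecutive inpatient days", {
  cl <- rbind(
    ps_claim("p1", c("2011-02-02", "2011-02-02"), dx = "", paid = c(50, 75)),
    ps_claim("p1", sprintf("2011-03-%02d", c(3, 4, 5, 9)), dx = "",
             setting = "inpatient", paid = 1000),
    ps_claim("p1", "2011-06-06", dx = "", setting = "er", paid = 200),
    ps_claim("p1", "2011-07-07", dx = "", setting = "pharmacy", paid = 30),
    ps_claim("p1", "2010-12-31", dx = "", paid = 999)  # baseline year: ignored
  )
  out <- derive_outcomes(cl, data.table(patient_id = character(),
                                        start_date = as.Date(character()),
                                        end_date = as.Date(character()),
                                        paid_usd = numeric()),
                         "p1", in_indirect_sample = 0L)
  expect_equal(out$outpatient_visits, 1L)
  expect_equal(out$hospitalizations, 2L)
  expect_equal(out$er_visits, 1L)
  expect_equal(out$cost_outpatient, 125)
  expect_equal(out$cost_inpatient, 4000)
  expect_equal(out$direct_cost_total, 4355)
  expect_true(is.na(out$std_days))
})

test_that("negative paid amounts are floored at zero with a warning", {
  cl <- ps_claim("p1", "2011-02-02", dx = "", paid = -10)
  expect_warning(
    out <- derive_outcomes(cl, data.table(patient_id = character(),
                                          start_date = as.Date(character()),
                                          end_date = as.Date(character()),
                                          paid_usd = numeric()),
                           "p1"),
    "floored")
  expect_equal(out$direct_cost_total, 0)
})

test_that("disability days count weekdays of the episode within the outcome year", {
  dis <- data.table(patient_id = c("p1", "p2", "p3"),
                    # Mon 2011-03-07 .. Fri 2011-03-18: 10 weekdays
                    # Sat 2011-01-01 .. Sun 2011-01-09: 5 weekdays
                    start_date = as.Date(c("2011-03-07", "2011-01-01", "2010-12-20")),
                    end_date = as.Date(c("2011-03-18", "2011-01-09", "2011-01-04")),
                    paid_usd = 0)
  out <- derive_outcomes(ps_claim("p0", "2011-01-01", dx = ""),
                         dis, c("p1", "p2", "p3", "p4"),
                         in_indirect_sample = c(1L, 1L, 1L, 1L))
  # p3's episode starts in 2010; only 2011-01-01..04 counts (Sat-Tue: 2 weekdays)
  expect_equal(out$std_days, c(10L, 5L, 2L, 0L))
})

test_that("count_weekdays matches a brute-force calendar scan", {
  set.seed(2)
  for (i in 1:25) {
    a <- as.Date("2010-01-01") + sample(0:700, 1)
    b <- a + sample(0:90, 1)
    brute <- sum(!format(seq(a, b, by = "day"), "%u") %in% c("6", "7"))
    expect_identical(count_weekdays(a, b), as.integer(brute))
  }
  expect_identical(count_weekdays(as.Date("2011-01-03"), as.Date("2011-01-02")), 0L)
})

test_that("build_cohort assembles a consistent analysis row per patient", {
  cfg <- tiny_config(n = 350, seed = 66)
  tb <- generate_population(cfg)
  res <- build_cohort(tb, wage = wage_config(23.09))
  co <- res$cohort
  expect_true(all(co$age >= 18))
  flags <- as.matrix(co[, comorbidity_names(), with = FALSE])
  expect_equal(co$any_comorbidity, as.integer(rowSums(flags) > 0))
  expect_true(all(abs(co$direct_cost_total -
                        (co$cost_outpatient + co$cost_er + co$cost_inpatient +
                           co$cost_pharmacy)) <= 0.01))
  expect_true(all(!is.na(co[in_indirect_sample == 1L, std_days])))
  expect_true(all(is.na(co[in_indirect_sample == 0L, std_days])))
  # severity group sizes partition the cohort
  expect_equal(sum(co$severity == "mild") + sum(co$severity == "moderate_severe"),
               nrow(co))
  # indirect costs follow the wage formula
  idx <- which(co$in_indirect_sample == 1L)
  expect_equal(co$indirect_cost[idx], co$std_days[idx] * 8 * 23.09)
})
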