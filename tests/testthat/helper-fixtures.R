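library(data.table)

# Small configuration for fast end-to-end tests.
tiny_config <- function(n = 400L, seed = 101L, ...) {
  sim_config(n_patients = n, seed = seed, ...)
}

full_enrollment <- function(ids, years = 2010:2011, plan = "PPO", hpm = 0L) {
  months <- unlist(lapply(years, function(y) sprintf("%d-%02d", y, 1:12)))
  data.table(patient_id = rep(ids, each = length(months)),
             year_month = rep(months, length(ids)),
             medical = 1L, pharmacy = 1L, plan_type = plan,
             hpm_std_eligible = hpm)
}

ps_claim <- function(id, date, dx = "696.1", setting = "outpatient", paid = 0) {
  data.table(patient_id = id, service_date = as.Date(date), setting = setting,
             dx1 = dx, dx2 = "", dx3 = "", dx4 = "", paid_usd = paid)
}

# Ten handcrafted patients: six satisfying every inclusion rule, four each
# violating exactly one rule (underage; same-date duplicate diagnoses; no
# baseline-year diagnosis; an enrollment gap).
handcrafted_tables <- function() {
  good <- sprintf("G%02d", 1:6)
  bad <- c("B_age", "B_samedate", "B_nobase", "B_gap")
  ids <- c(good, bad)
  demo <- data.table(
    patient_id = ids,
    birth_year = c(rep(1960L, 6), 1999L, 1960L, 1960L, 1960L),
    sex = rep(c("M", "F"), 5),
    region = rep(c("south", "west", "northeast", "north_central", "south"), 2)
  )
  claims <- rbind(
    ps_claim(rep(good, each = 2),
             rep(c("2010-02-01", "2011-03-05"), 6)),
    ps_claim("B_age", c("2010-02-01", "2011-03-05")),
    ps_claim("B_samedate", c("2010-02-01", "2010-02-01")),
    ps_claim("B_nobase", c("2011-02-01", "2011-03-05")),
    ps_claim("B_gap", c("2010-02-01", "2011-03-05"))
  )
  enroll <- full_enrollment(ids)
  enroll[patient_id == "B_gap" & year_month == "2010-07", pharmacy := 0L]
  raw_tables(claims = claims, enrollment = enroll, demographics = demo,
             disability = data.table(patient_id = character(),
                                     start_date = as.Date(character()),
                                     end_date = as.Date(character()),
                                     paid_usd = numeric()))
}

# Three-patient fixture backing the checked-in golden CSVs.
golden_tables <- function() {
  demo <- data.table(patient_id = c("A01", "A02", "A03"),
                     birth_year = c(1955L, 1972L, 1988L),
                     sex = c("F", "M", "F"),
                     region = c("south", "northeast", "missing"))
  claims <- rbind(
    ps_claim("A01", c("2010-01-15", "2010-09-02")),
    ps_claim("A01", "2011-04-10", dx = "", paid = 152.37),
    ps_claim("A01", "2011-04-11", dx = "", setting = "pharmacy", paid = 48.03),
    ps_claim("A02", c("2010-03-03", "2011-06-20"), dx = "696.8"),
    ps_claim("A02", c("2011-08-01", "2011-08-02", "2011-08-03"), dx = "",
             setting = "inpatient", paid = c(5200.00, 4100.50, 3999.50)),
    ps_claim("A03", c("2010-05-05", "2010-11-11"))
  )
  enroll <- full_enrollment(c("A01", "A02", "A03"))
  enroll[patient_id == "A03" & substr(year_month, 1, 4) == "2011",
         hpm_std_eligible := 1L]
  dis <- data.table(patient_id = "A03",
                    start_date = as.Date("2011-03-07"),
                    end_date = as.Date("2011-03-18"),
                    paid_usd = 1200.00)
  raw_tables(claims = claims, enrollment = enroll, demographics = demo,
             disability = dis)
}

# A minimal analysis-ready cohort data.table for direct model tests.
toy_cohort <- function(n = 1000L, seed = 5L) {
  set.seed(seed)
  dt <- data.table(
    patient_id = sprintf("T%05d", seq_len(n)),
    age = sample(18:90, n, replace = TRUE),
    sex = sample(c("M", "F"), n, replace = TRUE),
    region = sample(region_levels()[1:4], n, replace = TRUE),
    severity = sample(c("mild", "moderate_severe"), n, replace = TRUE,
                      prob = c(0.75, 0.25)),
    flag = rbinom(n, 1L, 0.3)
  )
  dt[, any_comorbidity := flag]
  lam <- 2 * exp(0.5 * dt$flag)
  dt[, outpatient_visits := rpois(n, lam)]
  dt[, hospitalizations := rpois(n, 0.2)]
  dt[, er_visits := rpois(n, 0.3)]
  pos <- rbinom(n, 1L, 0.8)
  dt[, direct_cost_total := pos * round(rgamma(n, 1, rate = 1 / (1000 * exp(0.4 * flag))), 2)]
  dt
}
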