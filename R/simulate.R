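#' @import data.table
NULL

#' Construct a raw-tables container
#'
#' Bundles the four raw administrative-claims tables the analysis consumes
#' (claims, enrollment, demographics, disability) plus, when produced by the
#' generator, an internal `truth` table labelling decoy patients and the
#' simulated patient-level quantities. `truth` is never written to disk.
#'
#' @param claims,enrollment,demographics,disability data.frames with the
#'   documented schemas (see [write_tables()]).
#' @param truth optional generator truth table.
#' @return An object of class `raw_tables`.
#' @export
raw_tables <- function(claims = empty_claims(), enrollment = empty_enrollment(),
                       demographics = empty_demographics(),
                       disability = empty_disability(), truth = NULL) {
  out <- list(claims = as.data.table(claims),
              enrollment = as.data.table(enrollment),
              demographics = as.data.table(demographics),
              disability = as.data.table(disability),
              truth = if (!is.null(truth)) as.data.table(truth))
  class(out) <- "raw_tables"
  out
}

empty_claims <- function() {
  data.table(patient_id = character(), service_date = as.Date(character()),
             setting = character(), dx1 = character(), dx2 = character(),
             dx3 = character(), dx4 = character(), paid_usd = numeric())
}
empty_enrollment <- function() {
  data.table(patient_id = character(), year_month = character(),
             medical = integer(), pharmacy = integer(), plan_type = character(),
             hpm_std_eligible = integer())
}
empty_demographics <- function() {
  data.table(patient_id = character(), birth_year = integer(),
             sex = character(), region = character())
}
empty_disability <- function() {
  data.table(patient_id = character(), start_date = as.Date(character()),
             end_date = as.Date(character()), paid_usd = numeric())
}

# Truncated-normal ages on [18, 99], rounded to whole years.
draw_ages <- function(n, mean, sd) {
  a <- stats::pnorm((18 - mean) / sd)
  b <- stats::pnorm((99 - mean) / sd)
  x <- mean + sd * stats::qnorm(a + stats::runif(n) * (b - a))
  pmin(99L, pmax(18L, as.integer(round(x))))
}

# Log effect of the comorbidity flag matrix Z for one outcome, with missing
# names treated as zero effect.
comorbidity_effect <- function(Z, effects, outcome = NULL) {
  cn <- colnames(Z)
  beta <- stats::setNames(numeric(length(cn)), cn)
  if (is.null(outcome)) {
    hit <- intersect(cn, names(effects))
    beta[hit] <- effects[hit]
  } else {
    hit <- intersect(cn, rownames(effects))
    beta[hit] <- effects[hit, outcome]
  }
  as.numeric(Z %*% beta)
}

#' Simulate the patient-level cohort truth
#'
#' Draws, per patient, the quantities the downstream models are about:
#' demographics, the severity proxy, independent comorbidity flags (or a
#' Gaussian-copula-coupled set when `comorbidity_correlation > 0`),
#' outcome-year Poisson utilization counts whose log means add base rate,
#' covariate effects and comorbidity log rate ratios, a semicontinuous
#' outcome-year direct cost (a point mass at zero, else a gamma draw with a
#' log-linear mean), and short-term-disability days for the HPM-eligible
#' subset. [generate_population()] decomposes these totals into claim lines;
#' this function is also usable directly as a fast analysis-ready cohort for
#' model validation at scale.
#'
#' @param config a [sim_config()] object.
#' @return A `data.table` with one row per patient: identifiers, demographics,
#'   `severity`, one 0/1 column per comorbidity, `any_comorbidity`,
#'   `outpatient_visits`, `hospitalizations`, `er_visits`,
#'   `direct_cost_total`, `std_eligible` and `std_days` (NA if not eligible).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  n <- config$n_patients
  cn <- names(config$comorbidity_prevalence)

  # stage 1: demographics + severity
  set.seed(sub_seed(config$seed, 1L))
  age <- draw_ages(n, config$age_mean, config$age_sd)
  male <- as.integer(stats::runif(n) < config$male_fraction)
  region <- region_levels()[1:4][findInterval(stats::runif(n),
                                              cumsum(config$region_probs)[1:3]) + 1L]
  region[stats::runif(n) < config$region_missing_fraction] <- "missing"
  sev <- as.integer(stats::runif(n) < config$severity_fraction)

  # stage 2: comorbidity flags
  set.seed(sub_seed(config$seed, 2L))
  rho <- config$comorbidity_correlation
  if (rho > 0) {
    common <- stats::rnorm(n)
    lat <- sqrt(rho) * common +
      sqrt(1 - rho) * matrix(stats::rnorm(n * length(cn)), n)
    Z <- 1L * (lat < matrix(stats::qnorm(config$comorbidity_prevalence),
                            n, length(cn), byrow = TRUE))
  } else {
    Z <- vapply(cn, function(j) {
      stats::rbinom(n, 1L, config$comorbidity_prevalence[[j]])
    }, integer(n))
    Z <- matrix(Z, nrow = n)
  }
  colnames(Z) <- cn

  age_c <- age - config$age_mean
  lin <- function(outcome) {
    ce <- config$covariate_effects[[outcome]]
    ce[["age"]] * age_c + ce[["male"]] * male + ce[["severity"]] * sev
  }

  # stage 3: utilization counts
  set.seed(sub_seed(config$seed, 3L))
  counts <- lapply(utilization_outcomes(), function(o) {
    lam <- config$utilization_base_rates[[o]] *
      exp(lin(o) + comorbidity_effect(Z, config$utilization_log_rate_effects, o))
    cap <- if (o == "hospitalization") 40L else 365L
    pmin(cap, stats::rpois(n, lam))
  })
  names(counts) <- utilization_outcomes()

  # stage 4: semicontinuous direct cost
  set.seed(sub_seed(config$seed, 4L))
  eta_pos <- stats::qlogis(config$cost_positive_prob) +
    comorbidity_effect(Z, config$cost_positive_logit_effects)
  positive <- stats::runif(n) < stats::plogis(eta_pos)
  mu <- config$cost_mean_base *
    exp(lin("cost") + comorbidity_effect(Z, config$cost_log_effects))
  draw <- stats::rgamma(n, shape = config$cost_shape, rate = config$cost_shape / mu)
  cost <- ifelse(positive, pmax(round(draw, 2), 0.01), 0)

  # stage 5: short-term-disability days
  set.seed(sub_seed(config$seed, 5L))
  sdm <- config$std_day_model
  eligible <- as.integer(stats::runif(n) < config$std_eligible_fraction)
  any_days <- stats::runif(n) >= sdm$zero_prob
  mean_d <- sdm$mean_days *
    exp(lin("std") + comorbidity_effect(Z, sdm$log_effects))
  d <- pmin(260L, pmax(1L, as.integer(round(
    stats::rgamma(n, shape = sdm$shape, rate = sdm$shape / mean_d)))))
  std_days <- ifelse(eligible == 1L, ifelse(any_days, d, 0L), NA_integer_)

  out <- data.table(
    patient_id = sprintf("P%07d", seq_len(n)),
    decoy_rule = NA_character_,
    birth_year = config$baseline_year - age,
    age = age,
    sex = ifelse(male == 1L, "M", "F"),
    region = region,
    severity = ifelse(sev == 1L, "moderate_severe", "mild")
  )
  for (j in cn) out[, (j) := Z[, j]]
  out[, `:=`(
    any_comorbidity = as.integer(rowSums(Z) > 0),
    outpatient_visits = counts$outpatient,
    hospitalizations = counts$hospitalization,
    er_visits = counts$er,
    direct_cost_total = cost,
    std_eligible = eligible,
    std_days = as.integer(std_days)
  )]
  out[]
}

# Distinct calendar days within a year for per-patient counts, fully
# vectorised: one random offset per patient plus even spacing guarantees
# distinctness (counts are capped at the year length upstream).
distinct_day_offsets <- function(counts, year_len) {
  keep <- counts > 0L
  v <- counts[keep]
  if (!length(v)) return(data.table(idx = integer(), day = integer()))
  off <- rep(sample.int(year_len, length(v), replace = TRUE) - 1L, v)
  k <- sequence(v)
  vv <- rep(v, v)
  day <- (off + floor((k - 1) * year_len / vv)) %% year_len + 1L
  data.table(idx = rep(which(keep), v), day = as.integer(day))
}

representative_code <- function(prefixes) {
  p <- prefixes[[1]]
  if (grepl("\\.", p)) p else paste0(p, ".0")
}

decoy_variants <- function() {
  c(age_under_18 = "age_under_18",
    single_dx = "insufficient_psoriasis_dx",
    same_date_dx = "insufficient_psoriasis_dx",
    no_baseline_dx = "no_baseline_dx",
    enrollment_gap = "not_continuously_enrolled")
}

#' Generate raw claims, enrollment, demographics and disability tables
#'
#' Expands the patient-level simulation of [simulate_cohort()] into raw
#' tables with the documented schemas: baseline-year psoriasis and
#' comorbidity diagnosis claims, severity-proxy treatment marker claims,
#' outcome-year outpatient/ER visit lines on distinct dates, multi-day
#' inpatient stays (separated so consecutive-day merging recovers the stay
#' count), pharmacy fills, per-line paid amounts that sum exactly to each
#' patient's simulated annual direct cost (a random gamma-weight split by
#' setting), 24 months of enrollment, and single short-term-disability
#' episodes whose in-year weekday count equals the simulated day total.
#' A configurable fraction of decoy patients, each violating exactly one
#' inclusion rule, is appended and labelled in the `truth` table.
#'
#' @param config a [sim_config()] object.
#' @param codes a [code_config()]; diagnosis codes written into the claims
#'   are drawn from these sets so the cohort builder (with the same codes)
#'   recovers the simulated flags.
#' @return A [raw_tables()] object (including the internal `truth` table).
#' @export
generate_population <- function(config, codes = code_config()) {
  truth <- simulate_cohort(config)
  y1 <- config$baseline_year
  y2 <- y1 + 1L
  d1 <- days_in_year(y1)
  d2 <- days_in_year(y2)
  n <- nrow(truth)
  cn <- names(config$comorbidity_prevalence)

  # stage 8: decoy patients, cycling over the five rule variants
  set.seed(sub_seed(config$seed, 8L))
  n_dec <- as.integer(round(config$decoy_fraction * config$n_patients))
  if (n_dec > 0) {
    variant <- rep(names(decoy_variants()), length.out = n_dec)
    dage <- draw_ages(n_dec, config$age_mean, config$age_sd)
    dage[variant == "age_under_18"] <- sample(10:17, sum(variant == "age_under_18"),
                                              replace = TRUE)
    dec <- data.table(
      patient_id = sprintf("D%07d", seq_len(n_dec)),
      decoy_rule = unname(decoy_variants()[variant]),
      decoy_variant = variant,
      birth_year = y1 - dage,
      age = dage,
      sex = ifelse(stats::runif(n_dec) < config$male_fraction, "M", "F"),
      region = region_levels()[1:4][findInterval(stats::runif(n_dec),
                                                 cumsum(config$region_probs)[1:3]) + 1L],
      severity = "mild"
    )
  } else {
    dec <- data.table()
  }
  truth[, decoy_variant := NA_character_]
  truth_all <- rbind(truth, dec, fill = TRUE)

  # stage 6: enrollment and plan type
  set.seed(sub_seed(config$seed, 6L))
  ids <- truth_all$patient_id
  u <- stats::runif(length(ids))
  plan <- ifelse(u < config$hmo_fraction, "HMO",
                 ifelse(u < config$hmo_fraction + 0.55, "PPO", "other"))
  months <- c(sprintf("%d-%02d", y1, 1:12), sprintf("%d-%02d", y2, 1:12))
  enrollment <- data.table(
    patient_id = rep(ids, each = 24L),
    year_month = rep(months, length(ids)),
    medical = 1L, pharmacy = 1L,
    plan_type = rep(plan, each = 24L),
    hpm_std_eligible = 0L
  )
  elig_ids <- truth$patient_id[truth$std_eligible == 1L]
  enrollment[patient_id %in% elig_ids & substr(year_month, 1, 4) == as.character(y2),
             hpm_std_eligible := 1L]
  if (n_dec > 0) {
    gap_ids <- dec$patient_id[dec$decoy_variant == "enrollment_gap"]
    enrollment[patient_id %in% gap_ids & year_month == sprintf("%d-06", y1),
               medical := 0L]
  }
  truth_all[, plan_type := plan]

  # stage 7: claim lines
  set.seed(sub_seed(config$seed, 7L))
  pieces <- list()
  blank_claims <- function(id, date, setting, dx1 = "", paid = 0) {
    data.table(patient_id = id, service_date = date, setting = setting,
               dx1 = dx1, dx2 = "", dx3 = "", dx4 = "", paid_usd = paid)
  }

  # baseline-year psoriasis diagnosis claims (two distinct dates)
  ps_code <- function(m) sample(codes$psoriasis_codes, m, replace = TRUE)
  o1 <- sample.int(d1, n, replace = TRUE) - 1L
  o2 <- (o1 + 1L + (sample.int(d1 - 1L, n, replace = TRUE) - 1L)) %% d1
  pieces$ps1 <- blank_claims(truth$patient_id, year_start(y1) + o1, "outpatient",
                             ps_code(n))
  pieces$ps2 <- blank_claims(truth$patient_id, year_start(y1) + o2, "outpatient",
                             ps_code(n))

  if (n_dec > 0) {
    v <- dec$decoy_variant
    do1 <- sample.int(d1, n_dec, replace = TRUE) - 1L
    do2 <- (do1 + 1L + (sample.int(d1 - 1L, n_dec, replace = TRUE) - 1L)) %% d1
    full2 <- function(keep) blank_claims(dec$patient_id[keep],
                                         year_start(y1) + do2[keep],
                                         "outpatient", ps_code(sum(keep)))
    ok <- v %in% c("age_under_18", "enrollment_gap")
    pieces$dec_a <- blank_claims(dec$patient_id[ok | v %in% c("single_dx", "same_date_dx")],
                                 year_start(y1) + do1[ok | v %in% c("single_dx", "same_date_dx")],
                                 "outpatient",
                                 ps_code(sum(ok | v %in% c("single_dx", "same_date_dx"))))
    pieces$dec_b <- full2(ok)
    sd <- v == "same_date_dx"
    pieces$dec_same <- blank_claims(dec$patient_id[sd], year_start(y1) + do1[sd],
                                    "outpatient", ps_code(sum(sd)))
    nb <- v == "no_baseline_dx"
    nb1 <- sample.int(d2, sum(nb), replace = TRUE) - 1L
    nb2 <- (nb1 + 1L + (sample.int(d2 - 1L, sum(nb), replace = TRUE) - 1L)) %% d2
    pieces$dec_nb1 <- blank_claims(dec$patient_id[nb], year_start(y2) + nb1,
                                   "outpatient", ps_code(sum(nb)))
    pieces$dec_nb2 <- blank_claims(dec$patient_id[nb], year_start(y2) + nb2,
                                   "outpatient", ps_code(sum(nb)))
  }

  # baseline-year comorbidity diagnosis claims
  for (j in cn) {
    hit <- truth[[j]] == 1L
    if (!any(hit)) next
    pieces[[paste0("co_", j)]] <- blank_claims(
      truth$patient_id[hit],
      year_start(y1) + sample.int(d1, sum(hit), replace = TRUE) - 1L,
      "outpatient", representative_code(codes$comorbidity_codes[[j]])
    )
  }

  # baseline-year severity-proxy treatment markers
  ms <- truth$severity == "moderate_severe"
  if (any(ms)) {
    marker <- sample(c(codes$systemic_therapy_markers, codes$phototherapy_markers),
                     sum(ms), replace = TRUE)
    pieces$sev <- blank_claims(truth$patient_id[ms],
                               year_start(y1) + sample.int(d1, sum(ms), replace = TRUE) - 1L,
                               ifelse(startsWith(marker, "RX_"), "pharmacy", "outpatient"),
                               marker)
  }

  # outcome-year utilization lines
  op <- distinct_day_offsets(truth$outpatient_visits, d2)
  pieces$op <- blank_claims(truth$patient_id[op$idx], year_start(y2) + op$day - 1L,
                            "outpatient")
  er <- distinct_day_offsets(truth$er_visits, d2)
  pieces$er <- blank_claims(truth$patient_id[er$idx], year_start(y2) + er$day - 1L,
                            "er")
  # inpatient stays: 8-day-spaced slots, stay length <= 6 days, so merging
  # consecutive-day lines downstream recovers exactly the simulated count
  st <- distinct_day_offsets(truth$hospitalizations, 44L)
  if (nrow(st)) {
    st[, start := (day - 1L) * 8L]
    st[, len := 1L + pmin(5L, stats::rpois(.N, 1.2))]
    ip <- st[rep(seq_len(.N), len)]
    ip[, day_off := sequence(st$len) - 1L]
    pieces$ip <- blank_claims(truth$patient_id[ip$idx],
                              year_start(y2) + ip$start + ip$day_off, "inpatient")
  }
  n_rx <- stats::rpois(n, 10)
  n_rx[truth$direct_cost_total > 0 & n_rx == 0L] <- 1L
  rx <- distinct_day_offsets(n_rx, d2)
  pieces$rx <- blank_claims(truth$patient_id[rx$idx], year_start(y2) + rx$day - 1L,
                            "pharmacy")

  claims <- rbindlist(pieces, use.names = TRUE)

  # tag a psoriasis dx onto one outcome-year outpatient visit per patient
  y2op <- claims[, which(setting == "outpatient" & service_date >= year_start(y2) &
                           dx1 == "")]
  if (length(y2op)) {
    first <- y2op[!duplicated(claims$patient_id[y2op])]
    claims[first, dx1 := ps_code(length(first))]
  }

  # split each patient's annual direct cost across outcome-year lines
  setting_alpha <- c(outpatient = 0.5, er = 1.0, inpatient = 3.0, pharmacy = 0.4)
  claims[, line_id := .I]
  y2rows <- claims[service_date >= year_start(y2) &
                     patient_id %in% truth$patient_id]
  y2rows[, w := stats::rgamma(.N, shape = setting_alpha[setting])]
  y2rows <- merge(y2rows,
                  truth[, .(patient_id, total = direct_cost_total)],
                  by = "patient_id")
  paid_tab <- y2rows[, .(line_id = line_id,
                         paid = if (total[1] > 0) split_to_cents(total[1], w) else 0),
                     by = patient_id]
  claims[paid_tab$line_id, paid_usd := paid_tab$paid]
  claims[, line_id := NULL]
  setorder(claims, patient_id, service_date, setting, dx1)

  # stage 9: short-term-disability episodes (one per patient with days > 0)
  set.seed(sub_seed(config$seed, 9L))
  y2days <- year_start(y2) + seq_len(d2) - 1L
  wk <- y2days[(as.integer(y2days) + 3L) %% 7L <= 4L]
  has_std <- which(!is.na(truth$std_days) & truth$std_days > 0L)
  if (length(has_std)) {
    dd <- truth$std_days[has_std]
    idx <- 1L + floor(stats::runif(length(dd)) * (length(wk) - dd + 1L))
    disability <- data.table(
      patient_id = truth$patient_id[has_std],
      start_date = wk[idx],
      end_date = wk[idx + dd - 1L],
      paid_usd = round(dd * 120, 2)
    )
    setorder(disability, patient_id)
  } else {
    disability <- empty_disability()
  }

  demographics <- truth_all[, .(patient_id, birth_year, sex, region)]
  setorder(demographics, patient_id)

  raw_tables(claims = claims, enrollment = enrollment,
             demographics = demographics, disability = disability,
             truth = truth_all)
}

#' Write raw tables to a directory of CSV files
#'
#' Emits `claims.csv`, `enrollment.csv`, `demographics.csv` and
#' `disability.csv` with the documented schemas. Dates are ISO-8601 and paid
#' amounts are fixed two-decimal strings, so output is byte-stable for
#' identical inputs and round-trips losslessly through [read_tables()].
#' The generator's internal truth table is not written.
#'
#' @param tables a [raw_tables()] object.
#' @param directory output directory (created if needed).
#' @return Invisibly, the paths of the four files.
#' @export
write_tables <- function(tables, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory, call. = FALSE)
  }
  cl <- copy(as.data.table(tables$claims))
  cl[, service_date := as.character(service_date)]
  cl[, paid_usd := sprintf("%.2f", paid_usd)]
  di <- copy(as.data.table(tables$disability))
  di[, `:=`(start_date = as.character(start_date),
            end_date = as.character(end_date),
            paid_usd = sprintf("%.2f", paid_usd))]
  paths <- file.path(directory, c("claims.csv", "enrollment.csv",
                                  "demographics.csv", "disability.csv"))
  tryCatch({
    fwrite(cl, paths[1], eol = "\n")
    fwrite(as.data.table(tables$enrollment), paths[2], eol = "\n")
    fwrite(as.data.table(tables$demographics), paths[3], eol = "\n")
    fwrite(di, paths[4], eol = "\n")
  }, error = function(e) {
    stop("failed writing tables under ", directory, ": ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(paths)
}

#' Read raw tables from a directory of CSV files
#'
#' Inverse of [write_tables()]; enforces the documented column types.
#'
#' @param directory directory containing the four CSV files.
#' @return A [raw_tables()] object (with `truth = NULL`).
#' @export
read_tables <- function(directory) {
  pth <- function(f) {
    p <- file.path(directory, f)
    if (!file.exists(p)) stop("missing input file: ", p, call. = FALSE)
    p
  }
  claims <- fread(pth("claims.csv"),
                  colClasses = list(character = c("patient_id", "setting",
                                                  "dx1", "dx2", "dx3", "dx4"),
                                    Date = "service_date",
                                    numeric = "paid_usd"))
  enrollment <- fread(pth("enrollment.csv"),
                      colClasses = list(character = c("patient_id", "year_month",
                                                      "plan_type"),
                                        integer = c("medical", "pharmacy",
                                                    "hpm_std_eligible")))
  demographics <- fread(pth("demographics.csv"),
                        colClasses = list(character = c("patient_id", "sex",
                                                        "region"),
                                          integer = "birth_year"))
  disability <- fread(pth("disability.csv"),
                      colClasses = list(character = "patient_id",
                                        Date = c("start_date", "end_date"),
                                        numeric = "paid_usd"))
  raw_tables(claims = claims, enrollment = enrollment,
             demographics = demographics, disability = disability)
}
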