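# Cohort construction: inclusion/exclusion cascade, severity proxy,
# comorbidity flags, Charlson index, and outcome-year utilization/cost
# derivation -- one analysis row per patient.

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Validate raw-table schemas
#'
#' @param tables a [raw_tables()] object or plain list of the four tables.
#' @return The tables, invisibly, if valid.
#' @export
validate_raw_tables <- function(tables) {
  require_columns(tables$claims, c("patient_id", "service_date", "setting",
                                   "dx1", "dx2", "dx3", "dx4", "paid_usd"),
                  "claims")
  require_columns(tables$enrollment, c("patient_id", "year_month", "medical",
                                       "pharmacy", "plan_type",
                                       "hpm_std_eligible"), "enrollment")
  require_columns(tables$demographics, c("patient_id", "birth_year", "sex",
                                         "region"), "demographics")
  require_columns(tables$disability, c("patient_id", "start_date", "end_date",
                                       "paid_usd"), "disability")
  invisible(tables)
}

# Long (patient_id, service_date, dx) table of non-blank diagnosis fields.
dx_long <- function(claims) {
  cl <- as.data.table(claims)
  out <- melt(cl[, .(patient_id, service_date, dx1, dx2, dx3, dx4)],
              id.vars = c("patient_id", "service_date"),
              value.name = "dx", variable.name = "slot")
  out[!is.na(dx) & dx != ""][, slot := NULL][]
}

matches_any_prefix <- function(dx, prefixes) {
  hit <- rep(FALSE, length(dx))
  for (p in prefixes) hit <- hit | startsWith(dx, p)
  hit
}

#' Inclusion/exclusion rule identifiers, in cascade order
#' @export
inclusion_rules <- function() {
  c("age_under_18", "insufficient_psoriasis_dx", "no_baseline_dx",
    "not_continuously_enrolled")
}

#' Apply the cohort inclusion/exclusion cascade
#'
#' A patient is included iff: age >= 18 at the start of the baseline year
#' (baseline year minus birth year); at least two psoriasis-coded claims on
#' distinct service dates across the two-year window; at least one of them in
#' the baseline year; and all 24 months enrolled with both medical and
#' pharmacy benefits. Exclusions are ledgered with the first failed rule in
#' cascade order. Two analysis-sample flags are attached to included
#' patients: `in_cost_sample` (no HMO coverage month in the outcome year) and
#' `in_indirect_sample` (any HPM short-term-disability-eligible month in the
#' outcome year).
#'
#' @param tables a [raw_tables()] object.
#' @param codes a [code_config()].
#' @param baseline_year first calendar year of the window.
#' @return A list: `cohort` (data.table of `patient_id`, `in_cost_sample`,
#'   `in_indirect_sample`), and `exclusions` (data.table of `patient_id`,
#'   `rule`).
#' @export
apply_inclusion <- function(tables, codes, baseline_year = 2010L) {
  validate_raw_tables(tables)
  demo <- as.data.table(tables$demographics)
  claims <- as.data.table(tables$claims)
  enroll <- as.data.table(tables$enrollment)

  claimed <- unique(c(claims$patient_id, tables$disability$patient_id))
  orphan <- setdiff(claimed, demo$patient_id)
  if (length(orphan)) {
    stop("data integrity: patient(s) present in claims/disability but not in ",
         "demographics: ", paste(utils::head(orphan, 5), collapse = ", "),
         call. = FALSE)
  }

  pats <- demo[, .(patient_id, age = baseline_year - birth_year)]

  dxl <- dx_long(claims)
  ps <- dxl[dx %in% codes$psoriasis_codes]
  ps_dates <- ps[, .(n_dates = uniqueN(service_date),
                     any_baseline = any(format(service_date, "%Y") ==
                                          as.character(baseline_year))),
                 by = patient_id]
  pats <- merge(pats, ps_dates, by = "patient_id", all.x = TRUE)
  pats[is.na(n_dates), `:=`(n_dates = 0L, any_baseline = FALSE)]

  months <- c(sprintf("%d-%02d", baseline_year, 1:12),
              sprintf("%d-%02d", baseline_year + 1L, 1:12))
  cont <- enroll[year_month %in% months & medical == 1L & pharmacy == 1L,
                 .(n_months = uniqueN(year_month)), by = patient_id]
  pats <- merge(pats, cont, by = "patient_id", all.x = TRUE)
  pats[is.na(n_months), n_months := 0L]

  pats[, rule := fifelse(age < 18, "age_under_18",
                 fifelse(n_dates < 2L, "insufficient_psoriasis_dx",
                 fifelse(!any_baseline, "no_baseline_dx",
                 fifelse(n_months < 24L, "not_continuously_enrolled",
                         NA_character_))))]

  y2 <- as.character(baseline_year + 1L)
  y2enroll <- enroll[substr(year_month, 1, 4) == y2]
  hmo <- y2enroll[plan_type == "HMO", unique(patient_id)]
  hpm <- y2enroll[hpm_std_eligible == 1L, unique(patient_id)]

  cohort <- pats[is.na(rule),
                 .(patient_id,
                   in_cost_sample = as.integer(!patient_id %in% hmo),
                   in_indirect_sample = as.integer(patient_id %in% hpm))]
  exclusions <- pats[!is.na(rule), .(patient_id, rule)]
  setorder(cohort, patient_id)
  setorder(exclusions, patient_id)
  list(cohort = cohort, exclusions = exclusions)
}

#' Classify psoriasis severity from baseline-year treatment claims
#'
#' Moderate-to-severe iff at least one baseline-year claim carries a
#' systemic-therapy or phototherapy marker; all other patients are mild.
#'
#' @param claims claims table.
#' @param codes a [code_config()].
#' @param patient_ids patients to classify.
#' @param baseline_year baseline calendar year.
#' @return data.table of `patient_id`, `severity` (`mild`/`moderate_severe`).
#' @export
classify_severity <- function(claims, codes, patient_ids, baseline_year = 2010L) {
  dxl <- dx_long(claims)
  markers <- c(codes$systemic_therapy_markers, codes$phototherapy_markers)
  trt <- dxl[dx %in% markers &
               format(service_date, "%Y") == as.character(baseline_year),
             unique(patient_id)]
  data.table(patient_id = patient_ids,
             severity = fifelse(patient_ids %in% trt, "moderate_severe", "mild"))
}

#' Flag study comorbidities from baseline-year diagnoses
#'
#' A comorbidity is flagged iff at least one baseline-year claim carries a
#' diagnosis matching any of its configured code prefixes. Flags are
#' ascertained independently per comorbidity.
#'
#' @inheritParams classify_severity
#' @return data.table with `patient_id` and one 0/1 column per configured
#'   comorbidity, plus `any_comorbidity`.
#' @export
flag_comorbidities <- function(claims, codes, patient_ids, baseline_year = 2010L) {
  dxl <- dx_long(claims)
  base <- dxl[format(service_date, "%Y") == as.character(baseline_year)]
  out <- data.table(patient_id = patient_ids)
  for (j in names(codes$comorbidity_codes)) {
    hit <- base[matches_any_prefix(dx, codes$comorbidity_codes[[j]]),
                unique(patient_id)]
    out[, (j) := as.integer(patient_id %in% hit)]
  }
  flags <- as.matrix(out[, names(codes$comorbidity_codes), with = FALSE])
  out[, any_comorbidity := as.integer(rowSums(flags) > 0)]
  out[]
}

#' Compute the Charlson Comorbidity Index from baseline-year diagnoses
#'
#' Weighted sum over configured Charlson conditions, each condition counted
#' at most once regardless of how many claims support it.
#'
#' @inheritParams classify_severity
#' @param cci_weights named list of `list(weight, codes)` per condition.
#' @return data.table of `patient_id`, `cci`.
#' @export
compute_cci <- function(claims, cci_weights, patient_ids, baseline_year = 2010L) {
  dxl <- dx_long(claims)
  base <- dxl[format(service_date, "%Y") == as.character(baseline_year)]
  score <- stats::setNames(integer(length(patient_ids)), patient_ids)
  for (cond in cci_weights) {
    hit <- base[matches_any_prefix(dx, cond$codes), unique(patient_id)]
    hit <- intersect(hit, patient_ids)
    score[hit] <- score[hit] + as.integer(cond$weight)
  }
  data.table(patient_id = patient_ids, cci = unname(score))
}

# One inpatient stay = a maximal run of consecutive calendar days with
# inpatient claims.
count_stays <- function(dates) {
  d <- sort(unique(as.integer(dates)))
  if (!length(d)) return(0L)
  1L + sum(diff(d) > 1L)
}

#' Derive outcome-year utilization counts, cost components and STD days
#'
#' Outpatient and ER visits are distinct (patient, service date) encounters
#' in the respective setting; hospitalizations are inpatient stays after
#' merging consecutive-day claims; cost components are sums of paid amounts
#' by setting (negative amounts floored at zero with a warning); short-term
#' disability days are weekdays covered by disability episodes intersected
#' with the outcome year -- 0 for eligible patients with no episode, missing
#' for patients outside the indirect-cost sample.
#'
#' @param claims claims table.
#' @param disability disability episode table.
#' @param patient_ids patients to derive outcomes for.
#' @param in_indirect_sample 0/1 vector aligned with `patient_ids`.
#' @param outcome_year calendar year of outcome measurement.
#' @return data.table keyed by `patient_id` with counts, cost components,
#'   `direct_cost_total` and `std_days`.
#' @export
derive_outcomes <- function(claims, disability, patient_ids,
                            in_indirect_sample = rep(1L, length(patient_ids)),
                            outcome_year = 2011L) {
  cl <- as.data.table(claims)[patient_id %in% patient_ids]
  cl <- cl[service_date >= year_start(outcome_year) &
             service_date <= year_end(outcome_year)]
  if (nrow(cl) && any(cl$paid_usd < 0)) {
    warning(sprintf("data integrity: %d negative paid amount(s) floored at 0",
                    sum(cl$paid_usd < 0)))
    cl[paid_usd < 0, paid_usd := 0]
  }

  out <- data.table(patient_id = patient_ids,
                    in_indirect_sample = as.integer(in_indirect_sample))

  visits <- function(set) {
    v <- cl[setting == set, .(n = uniqueN(service_date)), by = patient_id]
    out[, x := 0L][v, x := i.n, on = "patient_id"]
    n <- out$x; out[, x := NULL]; n
  }
  out[, outpatient_visits := visits("outpatient")]
  out[, er_visits := visits("er")]
  stays <- cl[setting == "inpatient", .(n = count_stays(service_date)),
              by = patient_id]
  out[, hospitalizations := 0L][stays, hospitalizations := i.n, on = "patient_id"]

  comp <- function(set) {
    v <- cl[setting == set, .(s = round(sum(paid_usd), 2)), by = patient_id]
    out[, x := 0][v, x := i.s, on = "patient_id"]
    s <- out$x; out[, x := NULL]; s
  }
  out[, cost_outpatient := comp("outpatient")]
  out[, cost_er := comp("er")]
  out[, cost_inpatient := comp("inpatient")]
  out[, cost_pharmacy := comp("pharmacy")]
  out[, direct_cost_total := round(cost_outpatient + cost_er + cost_inpatient +
                                     cost_pharmacy, 2)]

  dis <- as.data.table(disability)[patient_id %in% patient_ids]
  if (nrow(dis)) {
    dis <- dis[start_date <= year_end(outcome_year) &
                 end_date >= year_start(outcome_year)]
  }
  if (nrow(dis)) {
    dis[, days := count_weekdays(pmax(start_date, year_start(outcome_year)),
                                 pmin(end_date, year_end(outcome_year)))]
    dsum <- dis[, .(std_days = sum(days)), by = patient_id]
  } else {
    dsum <- data.table(patient_id = character(), std_days = integer())
  }
  out[, std_days := 0L][dsum, std_days := i.std_days, on = "patient_id"]
  out[in_indirect_sample == 0L, std_days := NA_integer_]
  out[, in_indirect_sample := NULL]
  out[]
}

#' Build the analysis-ready cohort from raw tables
#'
#' Runs the full cascade: inclusion/exclusion, severity classification,
#' comorbidity flagging, Charlson scoring, outcome derivation, and (when a
#' [wage_config()] is supplied) human-capital valuation of
#' short-term-disability days into an `indirect_cost` column.
#'
#' @param tables a [raw_tables()] object.
#' @param codes a [code_config()].
#' @param baseline_year first calendar year; outcomes use `baseline_year + 1`.
#' @param wage optional [wage_config()] for indirect costs.
#' @return A list: `cohort` (one analysis row per included patient) and
#'   `exclusions` (the exclusion ledger).
#' @export
build_cohort <- function(tables, codes = code_config(), baseline_year = 2010L,
                         wage = NULL) {
  inc <- apply_inclusion(tables, codes, baseline_year)
  if (nrow(inc$cohort) == 0L) {
    stop("no patients satisfy the inclusion criteria", call. = FALSE)
  }
  ids <- inc$cohort$patient_id
  demo <- as.data.table(tables$demographics)[patient_id %in% ids]
  cohort <- merge(inc$cohort,
                  demo[, .(patient_id, age = baseline_year - birth_year,
                           sex, region)],
                  by = "patient_id")
  cohort <- merge(cohort,
                  classify_severity(tables$claims, codes, ids, baseline_year),
                  by = "patient_id")
  cohort <- merge(cohort,
                  flag_comorbidities(tables$claims, codes, ids, baseline_year),
                  by = "patient_id")
  cohort <- merge(cohort, compute_cci(tables$claims, codes$cci_weights, ids,
                                      baseline_year),
                  by = "patient_id")
  cohort <- merge(cohort,
                  derive_outcomes(tables$claims, tables$disability,
                                  cohort$patient_id,
                                  cohort$in_indirect_sample,
                                  baseline_year + 1L),
                  by = "patient_id")
  if (!is.null(wage)) {
    cohort[, indirect_cost := hca_cost(std_days, wage)]
  } else {
    cohort[, indirect_cost := NA_real_]
  }
  setorder(cohort, patient_id)
  list(cohort = cohort[], exclusions = inc$exclusions)
}

#' Validate an analysis cohort's schema
#'
#' @param cohort a cohort data.frame.
#' @param comorbidities comorbidity columns expected present.
#' @return The cohort, invisibly, if valid.
#' @export
validate_cohort <- function(cohort, comorbidities = comorbidity_names()) {
  require_columns(cohort,
                  c("patient_id", "age", "sex", "region", "severity",
                    comorbidities, "any_comorbidity",
                    "outpatient_visits", "hospitalizations", "er_visits",
                    "direct_cost_total"),
                  "cohort")
  invisible(cohort)
}
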