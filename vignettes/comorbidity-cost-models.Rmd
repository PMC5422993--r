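---
title: "Modelling the incremental cost of comorbidities in psoriasis claims cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the incremental cost of comorbidities in psoriasis claims cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbidcost)
```

## The problem

Psoriasis rarely travels alone: psoriatic arthritis, cardiovascular disease,
depression, anxiety, diabetes, hyperlipidemia, hypertension, obesity,
cerebrovascular disease and peripheral vascular disease all occur at elevated
rates in psoriasis cohorts. Health-economic studies of US administrative
claims quantify what each comorbidity adds, per patient-year, to healthcare
utilization (outpatient visits, hospitalizations, ER visits), to direct
medical costs (outpatient, ER, inpatient and pharmacy paid amounts), and to
indirect costs from short-term disability. `comorbidcost` implements that
analysis end to end as tested, reusable code: a cohort is built from raw
claims over a two-calendar-year window (baseline year for eligibility,
severity, comorbidity ascertainment and covariates; the following year for
outcomes), and per-comorbidity regression models yield adjusted rate ratios
and incremental adjusted costs.

Because real claims databases of this kind are proprietary, the package
ships a synthetic-claims generator with the statistical structure the
analysis assumes. The generator is first-class, tested code: its defaults
emulate the published profile of a large US commercial/Medicare-supplemental
psoriasis cohort (N = 56,406), and because its data-generating law is fully
explicit, every estimator in the package can be validated against known
truth.

## The cohort definition

A patient enters the cohort iff all of:

1. age at the start of the baseline year (baseline year minus birth year,
   the usual claims convention) is at least 18;
2. at least two psoriasis-coded claims (ICD-9-CM 696.1 or 696.8 by default)
   on **distinct service dates** in the two-year window — same-day duplicate
   diagnoses collapse;
3. at least one of those claims falls in the baseline year;
4. all 24 months show enrollment with both medical and pharmacy benefits —
   a missing month row counts as non-enrolled (the conservative reading of
   continuous enrollment).

Exclusions are ledgered with the *first* failed rule in this order, so
attrition tables are reproducible. Two analysis flags are attached rather
than dropping rows: `in_cost_sample = 0` for patients with any HMO coverage
month in the outcome year (capitated claims understate true costs), and
`in_indirect_sample = 1` only for patients with short-term-disability (HPM)
eligibility in the outcome year. The HMO exclusion applies to the cost
analysis; by default the utilization models are also fitted on the cost
sample so that utilization and cost tables describe one N — this is
switchable (`models$utilization_sample = "all"`) because the source analyses
are ambiguous on the point.

Severity uses the standard treatment proxy: a patient is *moderate-to-severe*
iff at least one baseline-year claim carries a systemic-therapy or
phototherapy marker, otherwise *mild*. Comorbidities are flagged from
baseline-year diagnoses by code-prefix matching; one confirming claim
suffices (a stricter two-claim rule would be a config change, not a code
change). The Charlson Comorbidity Index is a weighted sum over configured
condition code sets, each condition counted once. All code sets are
configuration with small documented defaults: correctness tests target the
matching logic, not clinical completeness, and real analyses should supply
validated code dictionaries.

Outcome derivation: outpatient and ER visits are distinct (patient, date)
encounters per setting; hospitalizations merge consecutive-day inpatient
claims into stays (no transfer logic — nothing in claims supports one);
cost components are paid-amount sums per setting, with negative amounts
floored at zero under a logged warning; short-term-disability days are
weekdays covered by disability episodes intersected with the outcome year,
zero for eligible patients without episodes, missing outside the
indirect-cost sample.

## The models

**Utilization.** For each comorbidity $c$ and count outcome $Y$,

$$\log E[Y \mid z_c, x] = \beta_0 + \beta_c z_c + x^\top\gamma,$$

a Poisson GLM with $x$ = age (linear, in years), male, region (dummies,
with a "missing" level kept) and severity. The adjusted incidence rate
ratio is $\exp(\hat\beta_c)$ with Wald 95% CI
$\exp(\hat\beta_c \pm 1.96\,\widehat{SE})$. One model per comorbidity — not
a joint model — because the estimand is "patients with $c$ versus patients
without $c$", each contrast adjusted for demographics and severity only.
No exposure offset is needed: continuous enrollment gives every patient
exactly 12 outcome-year months. Model-based (expected-information) standard
errors are reported; overdispersion is a documented limitation (a
quasi-Poisson scale would widen CIs but not move the IRRs, and the
semicontinuous cost models are unaffected).

**Costs.** Annual cost is semicontinuous — a point mass at zero plus a
right-skewed positive part — so a two-part model is used: logistic
regression for $P(Y > 0 \mid z_c, x)$ on all rows, gamma regression with
log link for $E[Y \mid Y > 0, z_c, x]$ on the positive rows, both sharing
one design. Expected cost multiplies the two parts. The gamma dispersion is
the Pearson chi-square over $n - p$; with a log-link gamma GLM no smearing
retransformation is needed.

**Recycled prediction.** The incremental adjusted cost of comorbidity $c$
is a marginal-standardization (g-computation) contrast: predict every
patient's expected cost with $z_c$ forced to 1, then with $z_c$ forced to
0, holding all other covariates at observed values; average both; take the
difference. The standardization population is the full analysis sample, so
the two counterfactual populations are identical in everything except $c$.

**Bootstrap.** 95% CIs are percentile bootstrap over patients (the
independent sampling unit): resample rows with replacement, re-run the
*entire* fit-plus-standardization pipeline per replicate, and take the
2.5th/97.5th percentiles with the linear-interpolation quantile rule
(R type 7). The default is B = 1000 (B is not stated in the source
analyses; percentile is the default method for the same reason). Replicates
whose refit fails (e.g. a resample with no exposed patients) are dropped
and logged; more than 5% failures aborts with an error rather than
reporting a quietly biased interval.

## The synthetic generator

`sim_config()` fixes an explicit data-generating law; `simulate_cohort()`
draws the patient-level quantities and `generate_population()` decomposes
them into raw claim/enrollment/demographics/disability tables that the
cohort builder must reconstruct exactly (a property the tests assert).

What the defaults emulate, and where each number comes from:

* **Demographics** — age ~ Normal(51.63, 14.59²) truncated to [18, 99]
  (adult cohort with Medicare supplemental) and rounded to years; 50.01%
  male; region probabilities proportional to the published cohort's four
  regions, with 0.18% missing. The published summary counts themselves ship
  as `reference_counts()` and are the validation surface for the
  descriptive statistics.
* **Comorbidity flags** — independent Bernoulli draws at the published
  marginal prevalences (9.85% PsA … 34.33% hypertension). Only marginals
  are published, so independence is an explicit assumption; an exchangeable
  Gaussian-copula knob (`comorbidity_correlation`) can couple the latent
  scales while preserving marginals, but is off by default.
* **Severity** — Bernoulli(24.29%), drawn independently of the flags. Real
  cohorts show severity-comorbidity association (PsA especially); the
  generator deliberately does not, because no joint law is published.
  Consequences: severity-stratified descriptives on synthetic data are
  null, and the published bivariate p-values are validated on the published
  counts, not on simulation.
* **Utilization** — Poisson counts whose log mean adds a base rate
  (outpatient 8, hospitalization 0.08, ER 0.18 per year for a mild, female,
  average-age patient without comorbidity — realistic claims-cohort
  choices), covariate effects, and per-comorbidity log rate ratios set to
  the published adjusted IRRs (e.g. ln 2.60 for cardiovascular disease on
  hospitalization).
* **Direct cost** — zero with probability 0.05, else gamma with shape 0.5
  (strongly right-skewed, as cost data are) and log-linear mean; the
  per-comorbidity log cost ratios are the published
  adjusted-with/adjusted-without ratios, and `cost_mean_base = 6800` was
  derived from the generator's closed-form standardization so the
  no-cardiovascular-disease standardized cost is ≈ \$12.85k, matching the
  published magnitude. (The published incremental-cost column is not
  internally consistent with its own with/without columns, so the ratio —
  which is consistent — is what the generator anchors.)
* **Short-term disability** — eligibility 10.42%; given eligibility, zero
  days with probability 0.75, else a rounded gamma day count capped at 260
  weekdays/year, with log day ratios from the published indirect-cost
  ratios and `mean_days = 6.7` calibrated the same closed-form way to the
  ≈ \$830 standardized no-depression indirect cost at the 2011 average
  private-industry wage (\$23.09/h × 8 h/day — the wage is always caller
  config, never a package default).
* **Decoys** — 5% extra patients, each violating exactly one inclusion
  rule (underage; a single diagnosis claim; two same-date claims; no
  baseline-year diagnosis; an enrollment gap), labelled in the internal
  truth table so the cohort filter can be tested for *exactly* which
  patients it excludes and why.

Claim-line decomposition details that matter for correctness: visit dates
within a year use a random-offset even-spacing scheme that guarantees
distinct calendar dates; inpatient stays sit on an 8-day grid with stay
length at most 6 days so that consecutive-day merging recovers exactly the
simulated stay count; each patient's annual cost is split across their
outcome-year lines by random gamma weights per setting and rounded to cents
with the residual assigned to the largest line, so line sums reproduce the
annual totals exactly. Randomness flows from one seed through fixed
per-stage offsets, so adding a stage never perturbs another stage's draws,
and a fixed seed reproduces byte-identical CSV output.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: comorbidity co-occurrence and severity-comorbidity
association; seasonal or clustered visit timing; realistic ICD-9 coding
noise and miscoding; overdispersed counts (the generator is exactly Poisson
conditional on covariates); plan-design effects on costs (copays,
capitation, adjudication); partial-year enrollment patterns.

## Why the estimators recover the truth

The generator draws each comorbidity independently of the others and of the
covariates. A per-comorbidity model that omits the other nine is therefore
still correctly specified for its own conditional mean — the omitted
independent log-linear terms collapse into the intercept — so the Poisson
and gamma quasi-MLEs are consistent for the published-scale effects, and the
recycled-prediction contrast converges to the closed-form standardized
truth

$$p \cdot \mu_0 \cdot M_{\mathrm{age}}(\beta_{\mathrm{age}})
  \prod_j \left(\pi_j e^{\beta_j} + 1 - \pi_j\right)
  \cdot (e^{\beta_c} - 1),$$

which `true_incremental_cost()` evaluates exactly (the age moment generating
function is taken over the exact discretized truncated-normal age law).
This closed form is what the parameter-recovery and bootstrap-coverage
tests compare against.

## Numerical choices

* GLM fitting is IRLS (`stats::glm.fit`) with relative-deviance tolerance
  1e-10 and at most 100 iterations, followed by a few Fisher-scoring
  polish steps (stop when the step falls below 1e-11): the deviance-based
  stop alone leaves non-canonical-link coefficients only ~1e-6 accurate,
  while the polished solution has score at machine precision and matches an
  independent BFGS likelihood maximizer to better than 1e-6.
* The covariance is the inverse expected information (scaled by the Pearson
  dispersion for gamma), inverted after diagonal equilibration — claims
  designs mix an intercept, age in years and very sparse region dummies,
  which can push the raw information matrix past the conditioning limit.
* Rank-deficient designs error, naming the collinear columns; complete
  separation in the logistic part errors rather than returning divergent
  coefficients; gamma parts refuse nonpositive responses; all-zero or
  all-positive cost vectors direct the caller to a one-part model.
* Bootstrap replicates refit with a lean warm-started IRLS core using the
  same convergence contract (max coefficient change < 1e-8 or relative
  deviance change < 1e-10). Warm-starting at the full-sample coefficients
  changes only the iteration count, not the optimum. A resample that drops
  a rare region level entirely leaves an all-zero dummy column; its
  (irrelevant-for-that-resample) coefficient is set to zero.
* Ages are drawn by inverse-CDF truncated-normal sampling, so the exact
  discretized age law used by the closed-form truth is also the law
  actually sampled.

## Validation problem sizes

The test suite validates at sizes chosen to balance Monte-Carlo resolution
against run time: marginal-prevalence and moment checks at n = 50,000–56,406
(3-SE binomial/normal bands); cardiovascular hospitalization IRR recovery
inside the published interval [2.4, 2.8] over 100 cohorts of n = 50,000;
incremental-cost recovery and percentile-bootstrap coverage over 100 cohorts
of n = 5,000 with B = 200 (coverage accepted in the binomial [90, 99] band
around 95%); null-effect Wald coverage over 200 cohorts of n = 1,500;
unbiasedness of each GLM family over 40 replicates of n = 20,000. The demo
pipeline (n = 1,200, B = 25) runs in seconds; the full-scale reproduction in
`scripts/acceptance.R` (n = 56,406, B = 200) runs in about a minute.

## Known limitations

* Overdispersion: real utilization counts are overdispersed; model-based
  Poisson SEs are then anti-conservative. The IRR point estimates are
  unaffected; a robust/quasi-Poisson option is a natural extension.
* Independence assumptions inherited from the generator (above) mean
  synthetic validation cannot detect confounding-by-comorbidity-clustering
  that real data would present.
* Age enters all models linearly; the source analyses state no functional
  form, and nothing in the package precludes spline terms, but none are
  provided.
* The indirect-cost day law floors positive episodes at one day and caps at
  260; both compress extreme day ratios slightly relative to the configured
  log effects (the closed-form truth used in tests applies to direct costs,
  which have no such flooring).
* Costs are not inflation-adjusted and carry no cause-of-service
  attribution ("not cause related" costs by design).
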