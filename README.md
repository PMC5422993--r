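# comorbidcost

Incremental comorbidity burden in psoriasis claims cohorts: healthcare
utilization, direct medical costs, and short-term-disability indirect costs.

## What this package does, and for whom

Psoriasis patients carry high rates of comorbidity — psoriatic arthritis,
cardiovascular disease, depression, anxiety, diabetes, hyperlipidemia,
hypertension, obesity, cerebrovascular disease, peripheral vascular
disease — and health-economic analyses of US administrative claims quantify
what each condition adds per patient-year. `comorbidcost` implements that
analysis as a tested, reusable pipeline for outcomes researchers and
biostatisticians:

* **Cohort construction** from raw claims/enrollment/demographics/disability
  tables over a two-calendar-year window: adults with ≥ 2 psoriasis-coded
  claims (ICD-9-CM 696.1/696.8) on distinct dates, ≥ 1 in the baseline year,
  continuously enrolled with medical and pharmacy benefits, with a ledgered
  exclusion cascade; treatment-proxy severity (systemic therapy or
  phototherapy ⇒ moderate-to-severe); baseline-year comorbidity flags and
  Charlson index; outcome-year visit counts, stay-merged hospitalizations,
  cost components and short-term-disability days.
* **Descriptives**: severity-stratified counts/percentages and means/SDs with
  Pearson chi-square (no continuity correction) and Welch t-tests.
* **Utilization models**: per-comorbidity Poisson regression
  `count ~ comorbidity + age + male + region + severity`; adjusted incidence
  rate ratio IRR = exp(β̂) with Wald 95% CI exp(β̂ ± 1.96·SE).
* **Cost models**: two-part models — logistic for P(cost > 0), gamma
  (log link, Pearson dispersion) for positive cost — with the incremental
  adjusted cost of comorbidity *c* estimated by **recycled prediction**
  (marginal standardization): every patient is predicted under z_c = 1 and
  z_c = 0 with other covariates held at observed values, and the difference
  of the standardized means, E̅[Ŷ | all exposed] − E̅[Ŷ | all unexposed], is
  the incremental cost. 95% CIs are percentile bootstrap over patients, the
  full fit re-run per replicate.
* **Indirect costs** by the Human Capital Approach: days × 8 h × hourly wage
  (the wage is always caller configuration).
* **A synthetic-claims generator** (`sim_config()`, `generate_population()`)
  with a fully explicit, seeded data-generating law whose defaults emulate a
  published large US commercial-claims psoriasis cohort (N = 56,406) — so
  every estimator can be validated against closed-form truth
  (`true_incremental_cost()`).

## Worked example

```r
library(comorbidcost)
library(data.table)

cfg    <- sim_config(n_patients = 5000, seed = 42)   # defaults emulate the published cohort
tables <- generate_population(cfg)                   # raw claims/enrollment/demographics/disability
res    <- build_cohort(tables, wage = wage_config(23.09))  # 2011 BLS average hourly wage

res$exclusions[, .N, by = rule]
#>                         rule     N
#> 1:              age_under_18    50
#> 2: insufficient_psoriasis_dx   100
#> 3:            no_baseline_dx    50
#> 4: not_continuously_enrolled    50
```

All 5,000 eligible patients are retained; the 250 decoy patients the
generator planted (5%) are excluded under exactly the rule each was built to
violate. Severity-stratified descriptives:

```r
t1 <- summarize_cohort(res$cohort)
t1[variable %in% c("age", "psoriatic_arthritis", "hypertension"),
   .(variable, overall_n, overall = round(overall, 2), p = format_p(p_value))]
#>               variable overall_n overall      p
#> 1:                 age      5000   52.11 0.6431
#> 2: psoriatic_arthritis       473    9.46 0.4806
#> 3:        hypertension      1717   34.34 0.3280
```

Mean age 52.1 years and prevalences of 9.46% (PsA) and 34.34%
(hypertension) sit at the configured marginals; p-values compare
moderate-to-severe versus mild patients (null here by construction — the
generator draws severity independently). The adjusted hospitalization rate
ratio for cardiovascular disease, fitted on the non-HMO cost sample:

```r
cost <- res$cohort[in_cost_sample == 1L]
fit_irr_per_comorbidity(cost, "cardiovascular_disease", "hospitalization")
#>               comorbidity         outcome  irr ci_low ci_high p_value
#> 1: cardiovascular_disease hospitalization 2.35   2.06    2.68 5.5e-37
```

The generating rate ratio is 2.60; at n ≈ 4,400 the Wald interval covers
it. The incremental adjusted direct cost by recycled prediction with a
B = 200 percentile bootstrap:

```r
incremental_cost(cost, "cardiovascular_disease", B = 200, seed = 1)
#>               comorbidity adjusted_with adjusted_without incremental  ci_low ci_high
#> 1: cardiovascular_disease         23336          13100.4     10235.6  7933.8 13662.1
```

Read: if everyone in the sample had cardiovascular disease, the model
predicts mean annual direct costs of ≈ \$23.3k; if no one had it, ≈ \$13.1k;
the difference, ≈ \$10.2k (95% CI \$7.9k–\$13.7k), is the incremental
adjusted burden (the generator's closed-form truth for this configuration
is ≈ \$9.4k). `run_pipeline(config, out_dir)` (or
`inst/scripts/comorbidcost.R run`) executes the whole chain and writes
`table1.csv`, `irr.csv`, `direct_costs.csv`, `indirect_costs.csv`,
`cohort.csv`, `exclusions.csv` and a digest manifest.

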