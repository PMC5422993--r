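.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", ".I", ".N", ".SD", "patient_id", "service_date", "setting", "dx",
  "dx1", "dx2", "dx3", "dx4", "paid_usd", "year_month", "medical", "pharmacy",
  "plan_type", "hpm_std_eligible", "birth_year", "sex", "region", "severity",
  "decoy_rule", "decoy_variant", "any_comorbidity", "outpatient_visits",
  "hospitalizations", "er_visits", "direct_cost_total", "std_eligible",
  "std_days", "start_date", "end_date", "days", "rule", "age", "n_dates",
  "any_baseline", "n_months", "in_cost_sample", "in_indirect_sample",
  "cost_outpatient", "cost_er", "cost_inpatient", "cost_pharmacy",
  "indirect_cost", "cci", "line_id", "w", "total", "paid", "day", "start",
  "len", "day_off", "idx", "x", "i.n", "i.s", "i.std_days", "p_value",
  "p_display", "type", "overall", "modsev", "mild", "test", "irr", "ci_low",
  "ci_high"
))
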