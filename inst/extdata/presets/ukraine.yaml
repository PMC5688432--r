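# Reproductive-indicator preset: Ukraine (very low fertility driven by
# traditional-method use and abortion). Percent-scale values as published;
# converted on load. women_reproductive_age is a SYNTHETIC back-solved
# scaffold (see mali.yaml).
name: Ukraine
baseline_year: 2015
total_fertility_rate: 1.2
modern_cpr_pct: 48.0
traditional_cpr_pct: 19.0
unmet_need_pct: 10.0
proportion_married_pct: 60.0
ppi_months: 3.9
pct_childless_45_49: 3.5
abortions_per_1000_women: 42.0
pct_pregnancies_aborted: 38.0
stillbirth_rate_per_1000: 12.0
effectiveness_pct: 94.0
total_fecundity_published: 6.5
scenario_start_cpr_pct: 67.0
scenario_ramp_points_per_year: 1.0
reference_outputs:
  pregnancies: 860000.0
  unintended_pregnancies: 480000.0
  births: 470000.0
  miscarriages: 111800.0
  stillbirths: 5800.0
  abortions: 280000.0
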