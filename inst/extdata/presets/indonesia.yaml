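# Reproductive-indicator preset: Indonesia (high contraceptive use, low
# fertility). Percent-scale values as published; converted on load.
# women_reproductive_age is a SYNTHETIC back-solved scaffold (see mali.yaml).
name: Indonesia
baseline_year: 2015
total_fertility_rate: 2.6
modern_cpr_pct: 58.0
traditional_cpr_pct: 4.0
unmet_need_pct: 11.0
proportion_married_pct: 73.0
ppi_months: 3.8
pct_childless_45_49: 2.4
abortions_per_1000_women: 35.0
pct_pregnancies_aborted: 27.0
stillbirth_rate_per_1000: 18.0
effectiveness_pct: 96.0
total_fecundity_published: 12.9
scenario_start_cpr_pct: 62.0
scenario_ramp_points_per_year: 1.0
reference_outputs:
  pregnancies: 7900000.0
  unintended_pregnancies: 3300000.0
  births: 4900000.0
  miscarriages: 1027000.0
  stillbirths: 87000.0
  abortions: 1900000.0
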