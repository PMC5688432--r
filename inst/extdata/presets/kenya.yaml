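# Reproductive-indicator preset: Kenya (moderate contraceptive use, medium
# fertility). Percent-scale values as published; converted on load.
# women_reproductive_age is a SYNTHETIC back-solved scaffold (see mali.yaml).
# scenario_start_cpr_pct is the published scale-up scenario's starting
# prevalence, which differs from the baseline table's prevalence.
name: Kenya
baseline_year: 2015
total_fertility_rate: 3.9
modern_cpr_pct: 53.0
traditional_cpr_pct: 5.0
unmet_need_pct: 18.0
proportion_married_pct: 60.0
ppi_months: 8.6
pct_childless_45_49: 0.9
abortions_per_1000_women: 34.0
pct_pregnancies_aborted: 14.0
stillbirth_rate_per_1000: 26.0
effectiveness_pct: 96.0
total_fecundity_published: 22.9
scenario_start_cpr_pct: 42.0
scenario_ramp_points_per_year: 2.0
reference_outputs:
  pregnancies: 2200000.0
  unintended_pregnancies: 710000.0
  births: 1500000.0
  miscarriages: 286000.0
  stillbirths: 40000.0
  abortions: 340000.0
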