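# Reproductive-indicator preset: Mali (high fertility, low contraceptive use).
# Percent-scale values are stored exactly as published; they are converted to
# proportions on load. women_reproductive_age is a SYNTHETIC scaffold,
# back-solved so the crude birth conversion reproduces the published birth
# count at baseline; it is not published data.
name: Mali
baseline_year: 2015
total_fertility_rate: 6.1
modern_cpr_pct: 10.0
traditional_cpr_pct: 1.0
unmet_need_pct: 26.0
proportion_married_pct: 85.0
ppi_months: 11.7
pct_childless_45_49: 2.2
abortions_per_1000_women: 31.0
pct_pregnancies_aborted: 12.0
stillbirth_rate_per_1000: 44.0
effectiveness_pct: 95.0
total_fecundity_published: 13.3
scenario_start_cpr_pct: 10.0
scenario_ramp_points_per_year: 2.0
reference_outputs:
  pregnancies: 970000.0
  unintended_pregnancies: 308000.0
  births: 732000.0
  miscarriages: 126100.0
  stillbirths: 32000.0
  abortions: 110000.0
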