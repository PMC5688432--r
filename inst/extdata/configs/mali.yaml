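# Example run configuration: Mali, constant-prevalence counterfactual
# against a 2-point-per-year contraceptive scale-up over 10 years.
preset: Mali
parameters:
  rho: 0.31
scenarios:
- name: constant
  years:
    start: 2015
    end: 2025
- name: scaleup
  years:
    start: 2015
    end: 2025
  cpr:
    type: ramp
    points_per_year: 2.0
    start: 10.0
    cap: 85.0
output:
  rounding: 100
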