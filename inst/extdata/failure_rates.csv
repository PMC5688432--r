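method,failure_rate_percent
Female sterilization,0.50
Male sterilization,0.15
Oral pill,6.90
IUD,1.60
Injections,2.90
Implants,0.05
Male condom,9.80
Lactational amenorrhea,24.0
Traditional methods,78.0
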