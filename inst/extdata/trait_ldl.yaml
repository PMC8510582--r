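# Dichotomized "high cholesterol" example: LDL-C above 160 mg/dL.
# Trait distribution and PRS accuracy are illustrative round numbers.
trait_mean: 120
trait_sd: 30
threshold: 160
tail: upper
r2: 0.12
'n': 5
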