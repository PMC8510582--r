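# Dichotomized cognitive-impairment example: IQ below 70 is "affected".
# r2 is an illustrative PRS accuracy for intelligence (~5% of variance).
trait_mean: 100
trait_sd: 15
threshold: 70
tail: lower
r2: 0.052
'n': 5
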