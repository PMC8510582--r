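# Small genome-level validation run (synthetic cohort); seed required.
n_cases: 150
n_controls: 100
n_variants: 300
n_chromosomes: 5
target_r2_liab: 0.07
K: 0.01
n_couples: 500
n_embryos: 5
q: 0.02
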