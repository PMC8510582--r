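# Analytic LRP grid over prevalence and score accuracy, five embryos
K: [0.01, 0.05, 0.2]
r2: [0.05, 0.1, 0.3]
'n': 5
strategy: lrp
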