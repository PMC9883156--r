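seed: 7
folds: 5
pc_count: 4
scheme: odd_even
'n': 600
n_variants: 300
m_causal: 100
h2: 0.8
r: 0.6
generations: 3
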