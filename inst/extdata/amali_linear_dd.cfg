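species_label: Aphelinus mali
family: linear_dd
coefficients: 8.3, 254.8
lower_threshold: 8.3
upper_cutoff: auto
start_fraction: 0.5
events: G1 adults = 1, G2 adults = 2
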