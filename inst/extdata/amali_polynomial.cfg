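species_label: Aphelinus mali
family: polynomial
coefficients: -2.940e-3, -1.716e-4, 4.895e-4, -5.389e-5, 2.653e-6, -4.303e-8
lower_threshold: 8.3
upper_cutoff: auto
start_fraction: 0.5
events: G1 adults = 1, G2 adults = 2
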