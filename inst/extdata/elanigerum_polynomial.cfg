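species_label: Eriosoma lanigerum
family: polynomial
coefficients: 1.013e-3, -9.014e-4, -2.011e-4, 1.044e-4, -8.425e-6, 2.731e-7, -3.209e-9
lower_threshold: 5.2
upper_cutoff: auto
start_fraction: 0
events: first migration = 1
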