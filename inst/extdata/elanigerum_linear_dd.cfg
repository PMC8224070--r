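species_label: Eriosoma lanigerum
family: linear_dd
coefficients: 5.2, 267.6
lower_threshold: 5.2
upper_cutoff: auto
start_fraction: 0
events: first migration = 1
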