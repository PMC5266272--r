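# Default calibration of the two-pool heterodimer model.
# Units: synthesis AU/h per gene copy; degradation and binding rates 1/h.
s_A: 1.5
s_B: 1.0
N_A: 1
N_B: 1
d_free_A: 5.0
d_free_B: 5.0
d_complex: 1.0
k_on: 100
k_off: 0
tagged_copies_A: 1
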