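n_background: 30
n_scale: 60
e0: 0.3
e1: 8e-4
alpha: 1.6
e2: 0.15
tex0: 0.6
tex1: 1.2
leach0: 0.05
leach1: 0.3
eff_base: 0.6
eff_slope: 0.025
delay_penalty: 0.002
fym_n_content: 6
fym_avail_base: 0.45
fym_avail_week: -0.05
deposition: 25
n_out_per_t: 22
residue_c_per_t: 0.35
h_fym: 0.01
h_res: 0.004
soc_decay: 0.005
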