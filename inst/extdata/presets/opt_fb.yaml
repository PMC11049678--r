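input_phoneme_decay: 0.001
nphone_decay: 0.1
word_decay: 0.05
w_phoneme_to_nphone: 0.1
w_diphone_to_word: 0.05
w_singlephone_to_word: 0.01
w_word_word_inhibition: -0.01
fb_positive: 0.15
fb_negative: -0.05
gamma: 0.5
rho: 0.1
kernel_norm_power: 0.5
nphone_threshold: 0.2
word_threshold: 0.2
word_input_gain: 1.0
cycles_per_phoneme: 10
n_slots: 10
total_cycles: 100
act_min: -0.2
act_max: 1.0
rest: 0.0
preset: OPT_FB
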