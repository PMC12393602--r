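key	value
n_samples	140
n_calls_raw	161
n_samples_post_qc	139
n_qualifying	149
n_analysis_grade	113
planted_carriers_planted_dup_1	17
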