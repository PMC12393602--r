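synthetic cohort fixture (seed 42)
140 samples in 4 strata; 161 raw calls
planted loci: planted_dup_1
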