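locus_id	chrom	start	end	cnv_type
planted_dup_1	1	1000000	1300000	DUP
decoy_del	3	100000	350000	DEL
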