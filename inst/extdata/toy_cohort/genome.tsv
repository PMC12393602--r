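chrom	length
1	5000000
2	4000000
3	3000000
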