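gene_id
G0008
G0022
G0023
G0026
G0031
G0033
G0036
G0041
G0042
G0044
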