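gene_id
G0008
G0010
G0014
G0018
G0021
G0026
G0030
G0037
G0039
G0040
G0047
G0051
G0052
G0056
G0060
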