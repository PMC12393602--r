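gene_id	pli
G0001	0.388673
G0002	0.359703
G0003	0.061789
G0004	0.310966
G0005	0.455771
G0006	0.439932
G0007	0.228329
G0008	0.955756
G0009	0.164362
G0010	0.294831
G0011	0.126252
G0012	0.479322
G0013	0.120002
G0014	0.477251
G0015	0.43515
G0016	0.033331
G0017	0.070215
G0018	0.220879
G0019	0.040839
G0020	0.116303
G0021	0.45045
G0022	0.986653
G0023	0.964839
G0024	0.058144
G0025	0.192837
G0026	0.994853
G0027	0.237328
G0028	0.34522
G0029	0.248722
G0030	0.293819
G0031	0.998672
G0032	0.405475
G0033	0.995201
G0034	0.206596
G0035	0.098825
G0036	0.985192
G0037	0.311725
G0038	0.035235
G0039	0.198821
G0040	0.185444
G0041	0.96915
G0042	0.951858
G0043	0.47888
G0044	0.961443
G0045	0.267733
G0046	0.994173
G0047	0.041678
G0048	0.429568
G0049	0.236811
G0050	0.113812
G0051	0.179169
G0052	0.443011
G0053	0.443032
G0054	0.346133
G0055	0.998648
G0056	0.339216
G0057	0.496922
G0058	0.962848
G0059	0.112108
G0060	0.956636
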