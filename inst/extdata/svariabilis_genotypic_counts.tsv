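site	N	Ng
Dory Hill	34	20
Hill U 12	37	15
Hill U 13	37	22
Hill U 14	39	22
Hill U 15	39	19
Hill U 16	22	19
L Mongrel	38	20
Mac Ridge	15	10
MiniMatt33	34	16
MiniMatt34	35	26
MiniMatt35	39	15
MiniMatt36	24	14
MiniMatt37	39	30
Tasman1200	34	22
Z15	34	23
Z56	37	9
Z9	43	22
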