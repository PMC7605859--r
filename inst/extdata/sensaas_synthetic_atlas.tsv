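pair_name	hemisphere	volume_mm3	is_hub
F3t	L	2302	1
F3O	L	8830	0
F2p	L	5329	0
F1i	L	7664	0
PRECp	L	6164	0
INSa	L	2013	0
STS1	L	6672	0
STS2	L	4736	0
STS3	L	3810	1
STS4	L	4985	1
T1a	L	4096	0
T2a	L	7515	0
T2p	L	7219	0
T3p	L	1955	0
SMG	L	3471	0
AG	L	8640	0
FUSa	L	5678	0
PT	L	6908	0
F3t	R	2530	1
F3O	R	9476	0
F2p	R	5107	0
F1i	R	7402	0
PRECp	R	5615	0
INSa	R	1874	0
STS1	R	6328	0
STS2	R	4858	0
STS3	R	3861	1
STS4	R	5227	1
T1a	R	4017	0
T2a	R	7678	0
T2p	R	7272	0
T3p	R	2143	0
SMG	R	3768	0
AG	R	8360	0
FUSa	R	5421	0
PT	R	7132	0
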