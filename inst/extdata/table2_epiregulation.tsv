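gene_id	annotation	condition	e_change	placement	context	distance	delta
Csa6M010000.1	acetyltransferase	LL/LS	-2.04	DOWN	CHG	1438	0.12
Csa4M003670.1	Calvin cycle protein CP12-2	HL/HS	-1.82	CDS	CG	NA	0.26
Csa3M179130.1	MADS-box TF	HL/HS	-1.14	UP	CG	876	0.12
Csa6M095280.1	MADS-box TF	HL/HS	-2.15	UP	CHG	1283	0.15
Csa1M532310.1	MAPKKK	HL/HS	-2.72	UP	CG	1819	0.10
Csa3M171860.1	MLP	HL/HS	1.21	UP	CG	1635	-0.11
Csa5M606310.1	NAC domain protein	HL/HS	-1.84	CDS	CG	NA	0.18
Csa4M501830.1	phloem	HL/HS	-1.77	UP	CHG	1919	0.20
Csa1M168880.1	secoisolariciresinol dehydrogenase	HL/HS	-1.17	CDS	CG	NA	0.18
Csa7M414480.1	short-chain dehydrogenase reductase 3b	HL/HS	-1.05	CDS	CG	NA	0.14
Csa7M414480.1	short-chain dehydrogenase reductase 3b	HL/HS	-1.05	CDS	CG	NA	0.25
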