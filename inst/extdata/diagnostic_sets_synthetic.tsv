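set	reference_id	region_start	region_end	position	primary	allowed	weight
ethylene	AtETR1_synthetic	1	163	18	F	FY	1
ethylene	AtETR1_synthetic	1	163	25	I	IL	1
ethylene	AtETR1_synthetic	1	163	67	C	C	1
ethylene	AtETR1_synthetic	1	163	71	H	H	1
ethylene	AtETR1_synthetic	1	163	118	Y	YF	1
ethylene	AtETR1_synthetic	1	163	125	L	LI	1
cytokinin	AtAHK4_synthetic	96	345	155	F	FY	1
cytokinin	AtAHK4_synthetic	96	345	183	G	GA	1
cytokinin	AtAHK4_synthetic	96	345	217	D	DE	1
cytokinin	AtAHK4_synthetic	96	345	245	R	RK	1
cytokinin	AtAHK4_synthetic	96	345	276	P	P	1
cytokinin	AtAHK4_synthetic	96	345	301	T	TS	1
cytokinin	AtAHK4_synthetic	96	345	310	W	W	1
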