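variant	substitution	location	aa_change	private
56	A-T	HVS-2	-	yes
57	T-C	HVS-2	-	yes
60+T	-	HVS-2	-	yes
64	C-T	HVS-2	-	yes
73	A-G	HVS-2	-	no
249d	-	HVS-2	-	no
263	A-G	HVS-2	-	no
290-291d	-	HVS-2	-	no
309+C	-	HVS-2	-	no
315+C	-	HVS-2	-	no
455+T	-	HVS-2	-	yes
489	T-C	HVS-2	-	no
493	A-G	HVS-2	-	no
523-524d	-	HVS-2	-	no
662	T-C	12 S	-	yes
750	A-G	12 S	-	no
1438	A-G	12 S	-	no
2563	T-C	16 S	-	yes
2706	A-G	16 S	-	no
3552	T-A	ND1	-	no
4715	A-G	ND2	-	no
4769	A-G	ND2	-	no
5135	C-T	ND2	-	yes
7028	C-T	CO1	-	no
7196	C-A	CO1	-	no
8584	G-A	ATP6	A-T	no
8701	A-G	ATP6	T-A	no
8725	A-G	ATP6	T-A	yes
8860	A-G	ATP6	T-A	no
9540	T-C	CO3	-	no
9545	A-G	CO3	-	no
10398	A-G	ND3	T-A	no
10400	C-T	ND3	-	no
10873	T-C	ND4	-	no
11719	G-A	ND4	-	no
11914	G-A	ND4	-	no
12705	C-T	ND5	-	no
13263	A-G	ND5	-	no
14318	T-C	ND6	N-S	no
14766	C-T	CYTB	T-I	no
14783	T-C	CYTB	-	no
15043	G-A	CYTB	-	no
15301	G-A	CYTB	-	no
15326	A-G	CYTB	T-A	no
15487	A-T	CYTB	-	no
16124	T-C	HVS-1	-	yes
16223	C-T	HVS-1	-	no
16298	T-C	HVS-1	-	no
16325	T-C	HVS-1	-	no
16327	C-T	HVS-1	-	no
16519	T-C	HVS-1	-	no
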