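te_id	family	chrom	fpkm_ls	fpkm_ll	dmr_start	dmr_end	dmr_context	dmr_direction
Chr2.1737	unknown	Chr2	21.06	2.29	2895044	2895139	CG	down
Chr2.18932	LTR/Gypsy	Chr2	23.51	151.09	19247391	19247471	CHH	down
Chr2.18932	LTR/Gypsy	Chr2	23.51	151.09	19247523	19247585	CHG	up
Chr2.18932	LTR/Gypsy	Chr2	23.51	151.09	19247572	19247676	CG	up
Chr4.11395	LTR/Gypsy	Chr4	1344.08	7392.52	10157041	10157162	CHH	up
Chr4.11395	LTR/Gypsy	Chr4	1344.08	7392.52	10157974	10158139	CG	down
Chr4.11395	LTR/Gypsy	Chr4	1344.08	7392.52	10158526	10158581	CG	up
Chr4.11395	LTR/Gypsy	Chr4	1344.08	7392.52	10159108	10159175	CHH	down
Chr4.11395	LTR/Gypsy	Chr4	1344.08	7392.52	10160828	10160883	CG	up
Chr4.11395	LTR/Gypsy	Chr4	1344.08	7392.52	10161255	10161388	CG	down
Chr4.11395	LTR/Gypsy	Chr4	1344.08	7392.52	10166764	10167158	CG	up
Chr4.11405	LTR/Gypsy	Chr4	337.88	1704.24	10164610	10164937	CG	up
Chr4.11411	LTR/Gypsy	Chr4	0.32	38.66	10166764	10167158	CG	up
Chr4.11414	LTR/Gypsy	Chr4	2.57	103.78	10170488	10170582	CG	up
Chr4.11414	LTR/Gypsy	Chr4	2.57	103.78	10170660	10170721	CG	up
Chr4.11414	LTR/Gypsy	Chr4	2.57	103.78	10171222	10171380	CG	up
Chr4.11414	LTR/Gypsy	Chr4	2.57	103.78	10171278	10171358	CHG	up
Chr4.11418	LTR/Gypsy	Chr4	1581.50	8599.17	10174326	10174440	CHG	up
Chr4.11418	LTR/Gypsy	Chr4	1581.50	8599.17	10175334	10175441	CG	up
Chr4.11418	LTR/Gypsy	Chr4	1581.50	8599.17	10176583	10176641	CG	up
Chr4.11418	LTR/Gypsy	Chr4	1581.50	8599.17	10178622	10178718	CG	down
Chr4.11418	LTR/Gypsy	Chr4	1581.50	8599.17	10178873	10178967	CG	down
Chr4.11418	LTR/Gypsy	Chr4	1581.50	8599.17	10179267	10179323	CHG	down
Chr4.11418	LTR/Gypsy	Chr4	1581.50	8599.17	10179845	10179931	CG	down
Chr4.11418	LTR/Gypsy	Chr4	1581.50	8599.17	10180277	10180350	CHG	up
Chr4.11418	LTR/Gypsy	Chr4	1581.50	8599.17	10180434	10180598	CG	up
Chr4.11418	LTR/Gypsy	Chr4	1581.50	8599.17	10180810	10180884	CHG	down
Chr4.11418	LTR/Gypsy	Chr4	1581.50	8599.17	10181086	10181622	CG	down
Chr4.11418	LTR/Gypsy	Chr4	1581.50	8599.17	10181372	10181582	CHH	up
Chr4.11442	LTR/Gypsy	Chr4	41.50	293.74	10189425	10189483	CG	up
Chr6.14802	LTR/Gypsy	Chr6	1268.47	7504.71	13602334	13602466	CG	up
Chr6.14802	LTR/Gypsy	Chr6	1268.47	7504.71	13602478	13602580	CG	down
Chr6.14804	LTR/Gypsy	Chr6	837.91	5035.12	13603143	13603194	CG	down
Chr6.14804	LTR/Gypsy	Chr6	837.91	5035.12	13603385	13604182	CG	down
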