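dataset	source	mbg_a	mbg_x	pct_mbg_x	fbg_a	fbg_x	pct_fbg_x	ubg_a	ubg_x	pct_ubg_x
1	Brain	31	97	76	87	53	38	9102	1683	16
2	Head	87	31	26	194	45	19	6619	1367	17
3	Head	673	116	15	734	200	21	7039	1354	16
4	Head	1519	368	20	1350	289	18	5062	912	15
5	Head	161	40	20	273	70	21	9532	1813	16
6	Head	688	133	16	658	164	20	6496	1182	15
7	Tubule	1180	223	16	595	310	34	8789	1450	14
8	Whole fly	4285	642	13	3310	802	20	4106	707	15
9	Whole fly	1936	268	12	1494	364	20	3807	862	19
10	Whole fly	2490	324	12	3275	781	19	5021	957	16
11	Gonadectomized	565	87	13	537	99	16	4910	1086	18
12	Gonads	5589	841	13	2913	749	21	2963	498	14
13	Gonads	3634	526	13	3195	849	21	4784	767	14
14	Gonads	2301	369	14	1499	403	21	3321	761	19
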