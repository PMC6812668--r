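# SYNTHETIC stand-in for the consensus 46-rotamer suite table.
# The 46 rotamer ids are the consensus set; the rows for 1a, 1b, 2a and 2[
# are the published representative mean torsions; the remaining 42 mean
# vectors, all spreads and all frequencies are synthetic values constructed
# to respect the dd-family pucker structure and the per-family alpha/gamma
# modes, with >=60 deg separation between any two rotamers in at least one
# torsion. Angles in degrees on [0,360); spreads are circular sds; columns
# d1 e1 z1 a b g d2 = delta(i-1) epsilon(i-1) zeta(i-1) alpha beta gamma delta(i).
rotamer_id	d1	e1	z1	a	b	g	d2	sd_d1	sd_e1	sd_z1	sd_a	sd_b	sd_g	sd_d2	frequency
&a	82	150	289	295	110	52	85	3.3	9.1	11.2	10.2	13.5	8.1	4.5	41
#a	149	150	289	292	110	52	84	3.3	9.1	13.9	9.5	10.9	6.9	4.5	108
0a	144	280	215	291	240	49	83	4.5	9.6	14	10.5	10.9	8.9	4.3	186
0b	147	150	70	287	110	61	144	4.4	8.7	12.6	9	11	8	4	156
0i	144	280	143	69	240	172	85	3.4	9.3	10.9	10.5	10.1	7.3	4.7	66
1[	86	280	70	294	240	47	149	3.6	12	12.5	10.2	14	8.6	4	15
1a	81	212	289	295	174	54	81	3.9	8.1	10.5	9.3	10.6	8	3.6	4637
1b	84	215	289	300	177	58	145	3.8	8.2	14	11.8	10	7.5	3.9	502
1c	81	212	70	168	174	180	81	3.8	11.5	12.1	8.7	9.8	8.6	3.9	182
1e	81	280	215	301	240	181	82	4.6	9.8	14.2	10.4	12.3	7.7	3.5	136
1f	81	150	289	162	110	185	83	4.4	8.7	13	8.4	11.1	9.3	4.1	69
1g	83	280	143	171	240	59	82	4.5	12	11.4	11.6	11.1	7.5	4.2	111
1L	81	212	143	295	174	46	85	4.6	10.3	11.6	10	12.4	7.1	3.6	162
1m	80	150	70	289	110	56	80	4.7	11.2	11.1	11.4	12.5	7.4	4.7	16
1o	85	212	289	58	174	298	144	3.7	11.7	13.3	11.7	12.1	7.7	4.1	75
1t	83	150	143	172	110	183	148	4.2	11.4	11.5	8.9	13.2	7.1	4.3	43
1z	86	212	215	167	174	56	149	3.5	11.5	13.3	10.5	11.6	6.7	3.2	17
2[	146	259	291	292	210	54	148	4.6	8.5	11.2	9.5	12.6	9.5	4.3	284
2a	145	260	289	288	193	53	84	4.5	8.9	13.7	11.7	13.3	8	4.2	311
2h	146	280	215	289	240	184	82	3.4	9.3	14.1	9.8	14.2	8.1	4.5	48
2o	149	212	215	62	174	294	144	4.1	9.5	14.1	10.6	10	8.4	3.6	94
3a	80	280	289	293	240	53	85	4.7	9.3	13.7	10.1	11.9	8.4	3.5	20
3b	85	150	215	292	110	61	144	3.8	10	13.2	8.6	12.7	8.2	4.3	18
3d	85	212	289	67	174	57	81	4.5	9	12.8	10.8	11.6	7.6	4	33
4a	148	150	70	293	110	48	83	3.7	10.8	13.2	9.4	14.4	9.5	3.6	194
4b	146	212	215	288	174	58	148	3.8	10.4	11.5	11.1	13	6.8	4.2	137
4d	148	150	215	57	110	48	83	4.7	11.9	11.6	9.6	14	9.5	3.4	53
4g	144	212	70	164	174	49	83	3.5	11.8	13.3	11.2	12.6	7.3	3.5	31
4n	144	212	70	58	174	184	84	4.1	11.5	12.6	10.8	13.5	6.7	3.9	165
4p	145	212	143	60	174	55	145	4.6	11.2	13.2	9.4	14.1	8.5	4.7	131
4s	148	280	289	302	240	170	148	4.3	9.8	13.3	11.3	13.5	7.8	3.6	48
5d	84	150	215	67	110	47	83	4.7	11.5	12.9	10.4	12.3	8.3	3.8	87
5j	84	150	215	67	110	177	84	4.5	9.5	14.3	10.4	11.1	7.2	4.1	151
5q	87	150	70	66	110	181	146	3.7	11.2	10.7	9.4	12.5	7.9	3.4	136
5z	85	150	143	169	110	58	146	3.5	10.2	13.3	10.6	11.5	8.4	4	58
6d	148	280	143	58	240	48	82	4.1	9.6	14.2	10.7	14.1	6.6	3.3	23
6g	144	150	289	170	110	55	83	4.5	10.1	12.1	11.2	14.1	6.6	4.3	15
6j	146	150	289	57	110	184	85	3.4	10.9	13.1	11.2	11.7	9.3	3.9	80
6n	146	280	215	67	240	178	83	4.4	11	12	9.4	12.6	8.5	3.2	76
6p	145	150	70	72	110	52	145	4.2	10.7	10.8	8.5	10.2	7.8	4.1	100
7a	84	212	215	296	174	46	86	4	11.8	13.4	8.1	10.5	7.4	3.8	100
7d	80	280	143	59	240	52	84	4.7	8.6	11.7	9.8	12.9	8.9	3.6	33
7p	86	212	143	70	174	53	144	4	9.1	13	11.7	13.1	8.2	4.8	17
7r	83	280	289	161	240	60	146	3.9	11.7	14	8.1	11.1	7.2	3.7	40
8d	144	212	70	62	174	48	82	4	8.2	13.2	10	12.6	7	4.4	40
9a	82	150	143	297	110	53	83	4.3	11.2	14.1	8.4	9.7	9.2	4.2	190
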