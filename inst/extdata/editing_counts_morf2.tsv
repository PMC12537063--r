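site	gene	position	context	genotype	replicate	C	T
ndhB1	ndhB	149	TTCAA	WT	R1	10	312
ndhB1	ndhB	149	TTCAA	WT	R2	15	334
ndhB1	ndhB	149	TTCAA	WT	R3	7	146
ndhB1	ndhB	149	TTCAA	KRAB	R1	21	357
ndhB1	ndhB	149	TTCAA	KRAB	R2	11	296
ndhB1	ndhB	149	TTCAA	KRAB	R3	1	160
ndhB1	ndhB	149	TTCAA	P1_10	R1	15	355
ndhB1	ndhB	149	TTCAA	P1_10	R2	3	218
ndhB1	ndhB	149	TTCAA	P1_10	R3	4	123
ndhB1	ndhB	149	TTCAA	P1_12	R1	52	224
ndhB1	ndhB	149	TTCAA	P1_12	R2	25	151
ndhB1	ndhB	149	TTCAA	P1_12	R3	9	79
ndhB2	ndhB	467	TCCAG	WT	R1	8	308
ndhB2	ndhB	467	TCCAG	WT	R2	17	321
ndhB2	ndhB	467	TCCAG	WT	R3	3	151
ndhB2	ndhB	467	TCCAG	KRAB	R1	16	337
ndhB2	ndhB	467	TCCAG	KRAB	R2	16	278
ndhB2	ndhB	467	TCCAG	KRAB	R3	4	157
ndhB2	ndhB	467	TCCAG	P1_10	R1	14	336
ndhB2	ndhB	467	TCCAG	P1_10	R2	14	202
ndhB2	ndhB	467	TCCAG	P1_10	R3	14	110
ndhB2	ndhB	467	TCCAG	P1_12	R1	52	210
ndhB2	ndhB	467	TCCAG	P1_12	R2	20	150
ndhB2	ndhB	467	TCCAG	P1_12	R3	7	74
ndhB3	ndhB	586	TTCAT	WT	R1	10	306
ndhB3	ndhB	586	TTCAT	WT	R2	13	318
ndhB3	ndhB	586	TTCAT	WT	R3	1	152
ndhB3	ndhB	586	TTCAT	KRAB	R1	17	335
ndhB3	ndhB	586	TTCAT	KRAB	R2	8	283
ndhB3	ndhB	586	TTCAT	KRAB	R3	2	159
ndhB3	ndhB	586	TTCAT	P1_10	R1	15	330
ndhB3	ndhB	586	TTCAT	P1_10	R2	11	204
ndhB3	ndhB	586	TTCAT	P1_10	R3	4	115
ndhB3	ndhB	586	TTCAT	P1_12	R1	26	225
ndhB3	ndhB	586	TTCAT	P1_12	R2	11	158
ndhB3	ndhB	586	TTCAT	P1_12	R3	2	78
ndhB4	ndhB	746	TTCTC	WT	R1	7	272
ndhB4	ndhB	746	TTCTC	WT	R2	8	282
ndhB4	ndhB	746	TTCTC	WT	R3	3	135
ndhB4	ndhB	746	TTCTC	KRAB	R1	11	307
ndhB4	ndhB	746	TTCTC	KRAB	R2	5	260
ndhB4	ndhB	746	TTCTC	KRAB	R3	0	141
ndhB4	ndhB	746	TTCTC	P1_10	R1	10	301
ndhB4	ndhB	746	TTCTC	P1_10	R2	4	182
ndhB4	ndhB	746	TTCTC	P1_10	R3	4	99
ndhB4	ndhB	746	TTCTC	P1_12	R1	28	198
ndhB4	ndhB	746	TTCTC	P1_12	R2	13	138
ndhB4	ndhB	746	TTCTC	P1_12	R3	4	67
ndhB5	ndhB	830	TTCAG	WT	R1	3	295
ndhB5	ndhB	830	TTCAG	WT	R2	2	319
ndhB5	ndhB	830	TTCAG	WT	R3	2	142
ndhB5	ndhB	830	TTCAG	KRAB	R1	7	327
ndhB5	ndhB	830	TTCAG	KRAB	R2	6	271
ndhB5	ndhB	830	TTCAG	KRAB	R3	3	146
ndhB5	ndhB	830	TTCAG	P1_10	R1	8	321
ndhB5	ndhB	830	TTCAG	P1_10	R2	10	189
ndhB5	ndhB	830	TTCAG	P1_10	R3	1	112
ndhB5	ndhB	830	TTCAG	P1_12	R1	16	206
ndhB5	ndhB	830	TTCAG	P1_12	R2	7	135
ndhB5	ndhB	830	TTCAG	P1_12	R3	5	70
ndhB6	ndhB	836	TTCAG	WT	R1	11	285
ndhB6	ndhB	836	TTCAG	WT	R2	15	303
ndhB6	ndhB	836	TTCAG	WT	R3	6	137
ndhB6	ndhB	836	TTCAG	KRAB	R1	15	320
ndhB6	ndhB	836	TTCAG	KRAB	R2	15	257
ndhB6	ndhB	836	TTCAG	KRAB	R3	9	140
ndhB6	ndhB	836	TTCAG	P1_10	R1	25	304
ndhB6	ndhB	836	TTCAG	P1_10	R2	11	189
ndhB6	ndhB	836	TTCAG	P1_10	R3	18	94
ndhB6	ndhB	836	TTCAG	P1_12	R1	39	181
ndhB6	ndhB	836	TTCAG	P1_12	R2	26	117
ndhB6	ndhB	836	TTCAG	P1_12	R3	15	60
ndhB7	ndhB	872	CTCAT	WT	R1	5	290
ndhB7	ndhB	872	CTCAT	WT	R2	9	311
ndhB7	ndhB	872	CTCAT	WT	R3	3	142
ndhB7	ndhB	872	CTCAT	KRAB	R1	9	328
ndhB7	ndhB	872	CTCAT	KRAB	R2	12	258
ndhB7	ndhB	872	CTCAT	KRAB	R3	8	138
ndhB7	ndhB	872	CTCAT	P1_10	R1	11	317
ndhB7	ndhB	872	CTCAT	P1_10	R2	6	189
ndhB7	ndhB	872	CTCAT	P1_10	R3	3	107
ndhB7	ndhB	872	CTCAT	P1_12	R1	19	201
ndhB7	ndhB	872	CTCAT	P1_12	R2	7	132
ndhB7	ndhB	872	CTCAT	P1_12	R3	6	67
ndhB8	ndhB	1255	TCCAT	WT	R1	11	307
ndhB8	ndhB	1255	TCCAT	WT	R2	10	310
ndhB8	ndhB	1255	TCCAT	WT	R3	1	141
ndhB8	ndhB	1255	TCCAT	KRAB	R1	9	344
ndhB8	ndhB	1255	TCCAT	KRAB	R2	10	291
ndhB8	ndhB	1255	TCCAT	KRAB	R3	3	140
ndhB8	ndhB	1255	TCCAT	P1_10	R1	16	330
ndhB8	ndhB	1255	TCCAT	P1_10	R2	8	202
ndhB8	ndhB	1255	TCCAT	P1_10	R3	1	113
ndhB8	ndhB	1255	TCCAT	P1_12	R1	33	232
ndhB8	ndhB	1255	TCCAT	P1_12	R2	21	140
ndhB8	ndhB	1255	TCCAT	P1_12	R3	7	70
ndhB9	ndhB	1481	ACCAG	WT	R1	16	252
ndhB9	ndhB	1481	ACCAG	WT	R2	11	232
ndhB9	ndhB	1481	ACCAG	WT	R3	10	106
ndhB9	ndhB	1481	ACCAG	KRAB	R1	17	276
ndhB9	ndhB	1481	ACCAG	KRAB	R2	12	219
ndhB9	ndhB	1481	ACCAG	KRAB	R3	3	109
ndhB9	ndhB	1481	ACCAG	P1_10	R1	23	273
ndhB9	ndhB	1481	ACCAG	P1_10	R2	12	164
ndhB9	ndhB	1481	ACCAG	P1_10	R3	10	90
ndhB9	ndhB	1481	ACCAG	P1_12	R1	37	172
ndhB9	ndhB	1481	ACCAG	P1_12	R2	20	110
ndhB9	ndhB	1481	ACCAG	P1_12	R3	15	50
ndhD1	ndhD	2	CACGA	WT	R1	279	287
ndhD1	ndhD	2	CACGA	WT	R2	148	150
ndhD1	ndhD	2	CACGA	WT	R3	132	111
ndhD1	ndhD	2	CACGA	KRAB	R1	235	243
ndhD1	ndhD	2	CACGA	KRAB	R2	187	157
ndhD1	ndhD	2	CACGA	KRAB	R3	133	120
ndhD1	ndhD	2	CACGA	P1_10	R1	307	249
ndhD1	ndhD	2	CACGA	P1_10	R2	181	138
ndhD1	ndhD	2	CACGA	P1_10	R3	153	81
ndhD1	ndhD	2	CACGA	P1_12	R1	362	56
ndhD1	ndhD	2	CACGA	P1_12	R2	194	42
ndhD1	ndhD	2	CACGA	P1_12	R3	140	22
ndhD2	ndhD	383	ATCAT	WT	R1	10	498
ndhD2	ndhD	383	ATCAT	WT	R2	10	265
ndhD2	ndhD	383	ATCAT	WT	R3	6	224
ndhD2	ndhD	383	ATCAT	KRAB	R1	12	436
ndhD2	ndhD	383	ATCAT	KRAB	R2	14	313
ndhD2	ndhD	383	ATCAT	KRAB	R3	7	224
ndhD2	ndhD	383	ATCAT	P1_10	R1	27	478
ndhD2	ndhD	383	ATCAT	P1_10	R2	11	294
ndhD2	ndhD	383	ATCAT	P1_10	R3	13	200
ndhD2	ndhD	383	ATCAT	P1_12	R1	30	355
ndhD2	ndhD	383	ATCAT	P1_12	R2	9	224
ndhD2	ndhD	383	ATCAT	P1_12	R3	7	139
ndhD3	ndhD	674	ATCAC	WT	R1	41	430
ndhD3	ndhD	674	ATCAC	WT	R2	19	244
ndhD3	ndhD	674	ATCAC	WT	R3	11	201
ndhD3	ndhD	674	ATCAC	KRAB	R1	27	405
ndhD3	ndhD	674	ATCAC	KRAB	R2	15	290
ndhD3	ndhD	674	ATCAC	KRAB	R3	14	207
ndhD3	ndhD	674	ATCAC	P1_10	R1	27	446
ndhD3	ndhD	674	ATCAC	P1_10	R2	9	280
ndhD3	ndhD	674	ATCAC	P1_10	R3	11	200
ndhD3	ndhD	674	ATCAC	P1_12	R1	23	335
ndhD3	ndhD	674	ATCAC	P1_12	R2	15	202
ndhD3	ndhD	674	ATCAC	P1_12	R3	9	129
ndhD4	ndhD	878	TTCAA	WT	R1	62	397
ndhD4	ndhD	878	TTCAA	WT	R2	39	215
ndhD4	ndhD	878	TTCAA	WT	R3	36	168
ndhD4	ndhD	878	TTCAA	KRAB	R1	51	363
ndhD4	ndhD	878	TTCAA	KRAB	R2	38	258
ndhD4	ndhD	878	TTCAA	KRAB	R3	34	183
ndhD4	ndhD	878	TTCAA	P1_10	R1	97	367
ndhD4	ndhD	878	TTCAA	P1_10	R2	39	250
ndhD4	ndhD	878	TTCAA	P1_10	R3	47	154
ndhD4	ndhD	878	TTCAA	P1_12	R1	110	233
ndhD4	ndhD	878	TTCAA	P1_12	R2	63	145
ndhD4	ndhD	878	TTCAA	P1_12	R3	34	102
ndhD5	ndhD	887	TCCCG	WT	R1	52	403
ndhD5	ndhD	887	TCCCG	WT	R2	42	216
ndhD5	ndhD	887	TCCCG	WT	R3	32	171
ndhD5	ndhD	887	TCCCG	KRAB	R1	49	362
ndhD5	ndhD	887	TCCCG	KRAB	R2	32	257
ndhD5	ndhD	887	TCCCG	KRAB	R3	27	187
ndhD5	ndhD	887	TCCCG	P1_10	R1	54	402
ndhD5	ndhD	887	TCCCG	P1_10	R2	25	263
ndhD5	ndhD	887	TCCCG	P1_10	R3	37	163
ndhD5	ndhD	887	TCCCG	P1_12	R1	51	291
ndhD5	ndhD	887	TCCCG	P1_12	R2	36	173
ndhD5	ndhD	887	TCCCG	P1_12	R3	24	107
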