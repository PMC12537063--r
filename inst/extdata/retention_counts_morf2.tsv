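genotype	replicate	unspliced	aligned
WT	R1	4	531
WT	R2	4	439
WT	R3	4	196
KRAB	R1	10	614
KRAB	R2	15	471
KRAB	R3	5	215
P1_10	R1	21	585
P1_10	R2	8	337
P1_10	R3	4	186
P1_12	R1	40	501
P1_12	R2	27	330
P1_12	R3	9	122
WT_RL	R1	2	594
WT_RL	R2	1	270
WT_RL	R3	1	96
g_RL	R1	9	756
g_RL	R2	9	310
g_RL	R3	4	136
sil_RL	R1	34	787
sil_RL	R2	14	233
sil_RL	R3	6	70
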