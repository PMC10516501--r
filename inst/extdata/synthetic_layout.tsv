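channel	batch	cell_line	time_point_h	phase	fraction	replicate
1	WT_r1	WT	0	DMSO	soluble	1
2	WT_r1	WT	0	DMSO	insoluble	1
3	WT_r1	WT	12	treatment	soluble	1
4	WT_r1	WT	12	treatment	insoluble	1
5	WT_r1	WT	36	recovery	soluble	1
6	WT_r1	WT	36	recovery	insoluble	1
7	WT_r1	WT	60	recovery	soluble	1
8	WT_r1	WT	60	recovery	insoluble	1
9	WT_r1	pool	NA	pool	pooled_control	1
1	WT_r2	WT	0	DMSO	soluble	2
2	WT_r2	WT	0	DMSO	insoluble	2
3	WT_r2	WT	12	treatment	soluble	2
4	WT_r2	WT	12	treatment	insoluble	2
5	WT_r2	WT	36	recovery	soluble	2
6	WT_r2	WT	36	recovery	insoluble	2
7	WT_r2	WT	60	recovery	soluble	2
8	WT_r2	WT	60	recovery	insoluble	2
9	WT_r2	pool	NA	pool	pooled_control	2
1	WT_r3	WT	0	DMSO	soluble	3
2	WT_r3	WT	0	DMSO	insoluble	3
3	WT_r3	WT	12	treatment	soluble	3
4	WT_r3	WT	12	treatment	insoluble	3
5	WT_r3	WT	36	recovery	soluble	3
6	WT_r3	WT	36	recovery	insoluble	3
7	WT_r3	WT	60	recovery	soluble	3
8	WT_r3	WT	60	recovery	insoluble	3
9	WT_r3	pool	NA	pool	pooled_control	3
1	CHOP_KO_r1	CHOP_KO	0	DMSO	soluble	1
2	CHOP_KO_r1	CHOP_KO	0	DMSO	insoluble	1
3	CHOP_KO_r1	CHOP_KO	12	treatment	soluble	1
4	CHOP_KO_r1	CHOP_KO	12	treatment	insoluble	1
5	CHOP_KO_r1	CHOP_KO	36	recovery	soluble	1
6	CHOP_KO_r1	CHOP_KO	36	recovery	insoluble	1
7	CHOP_KO_r1	CHOP_KO	60	recovery	soluble	1
8	CHOP_KO_r1	CHOP_KO	60	recovery	insoluble	1
9	CHOP_KO_r1	pool	NA	pool	pooled_control	1
1	CHOP_KO_r2	CHOP_KO	0	DMSO	soluble	2
2	CHOP_KO_r2	CHOP_KO	0	DMSO	insoluble	2
3	CHOP_KO_r2	CHOP_KO	12	treatment	soluble	2
4	CHOP_KO_r2	CHOP_KO	12	treatment	insoluble	2
5	CHOP_KO_r2	CHOP_KO	36	recovery	soluble	2
6	CHOP_KO_r2	CHOP_KO	36	recovery	insoluble	2
7	CHOP_KO_r2	CHOP_KO	60	recovery	soluble	2
8	CHOP_KO_r2	CHOP_KO	60	recovery	insoluble	2
9	CHOP_KO_r2	pool	NA	pool	pooled_control	2
1	CHOP_KO_r3	CHOP_KO	0	DMSO	soluble	3
2	CHOP_KO_r3	CHOP_KO	0	DMSO	insoluble	3
3	CHOP_KO_r3	CHOP_KO	12	treatment	soluble	3
4	CHOP_KO_r3	CHOP_KO	12	treatment	insoluble	3
5	CHOP_KO_r3	CHOP_KO	36	recovery	soluble	3
6	CHOP_KO_r3	CHOP_KO	36	recovery	insoluble	3
7	CHOP_KO_r3	CHOP_KO	60	recovery	soluble	3
8	CHOP_KO_r3	CHOP_KO	60	recovery	insoluble	3
9	CHOP_KO_r3	pool	NA	pool	pooled_control	3
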