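strain	dup_chrom_kb	lines	total_mutations	on_dup_chrom	sub_coding	sub_noncoding	indel_coding	indel_noncoding	missense	nonsense	silent
WT	NA	3	5	NA	3	1	1	0	2	0	1
D1	230	3	23	7	5	11	2	5	3	1	1
D2	813	3	32	8	3	11	3	15	2	0	1
D5	576	3	26	5	15	6	0	5	10	0	5
D8	562	3	37	9	15	15	1	6	10	1	4
D9	439	3	18	5	8	5	0	5	6	1	1
D10	745	2	48	14	19	10	13	6	11	1	7
D11	666	3	42	7	13	10	5	14	8	0	5
D12	1080	3	30	11	13	8	2	7	9	0	4
D13	924	2	30	9	9	7	2	12	6	0	3
D14	784	2	24	7	8	14	0	2	6	0	2
D15	1091	3	33	12	13	13	1	6	10	1	2
D16	948	2	30	11	13	9	2	6	8	2	3
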