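chrom	n_lines_with_introgression	n_introgressions	n_bins
1	53	54	62
2	91	99	82
3	57	69	55
4	94	101	91
5	145	171	156
6	93	103	86
7	72	78	50
8	97	103	69
9	84	103	97
10	109	126	98
11	208	236	128
12	104	129	75
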