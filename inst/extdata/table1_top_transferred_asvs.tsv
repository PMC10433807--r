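asv_id	taxon	pct_identity	n_maternal	n_transfers	n_both	n_10d	n_3mo
1	Lactobacillus crispatus	100	380	61	0	57	4
2	Bifidobacterium breve	98	43	28	11	7	10
3	Actinomyces neuii subsp. anitratus	100	232	23	1	16	6
4	Bifidobacterium longum subsp. longum	100	25	15	5	5	5
5	Lactobacillus gasseri	100	146	12	0	7	5
6	Shigella sonnei	98.7	23	12	6	3	3
7	Escherichia coli	100	15	8	2	2	4
8	Lactobacillus jensenii	100	203	7	0	7	0
9	Bifidobacterium dentium	98.7	16	4	0	3	1
10	Escherichia coli	99.3	9	3	0	3	0
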