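asv_id	taxon	pct_identity	n_maternal	n_transfers	n_both	n_10d	n_3mo
1	Bifidobacterium adolescentis	100	1	1	0	1	0
2	Bifidobacterium adolescentis	98.7	1	1	0	0	1
3	Bifidobacterium bifidum	98.7	4	2	0	0	2
4	Bifidobacterium breve	98	43	28	11	7	10
5	Bifidobacterium breve	98.7	6	3	2	1	0
6	Bifidobacterium breve	97.3	3	3	0	2	1
7	Bifidobacterium breve	97.3	4	2	0	0	2
8	Bifidobacterium breve	98	10	1	0	1	0
9	Bifidobacterium breve	98	1	1	1	0	0
10	Bifidobacterium breve	98	1	1	0	1	0
11	Bifidobacterium breve	97.3	2	1	0	0	1
12	Bifidobacterium dentium	98.7	16	4	0	3	1
13	Bifidobacterium longum subsp. infantis	100	2	1	1	0	0
14	Bifidobacterium longum subsp. longum	100	25	15	5	5	5
15	Bifidobacterium longum subsp. longum	99.3	12	3	0	3	0
16	Bifidobacterium longum subsp. longum	99.3	3	1	0	0	1
17	Bifidobacterium pseudocatenulatum	99.3	3	1	0	1	0
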