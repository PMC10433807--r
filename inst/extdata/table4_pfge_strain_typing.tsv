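species	grouping	level	identical	nonidentical
Bifidobacterium	delivery_mode	vaginal	10	5
Bifidobacterium	delivery_mode	elective_CS	7	5
Bifidobacterium	delivery_mode	emergency_CS	5	1
Bifidobacterium	ip_antibiotics	unexposed	8	3
Bifidobacterium	ip_antibiotics	exposed	14	8
Bifidobacterium	time_point	10_days	34	9
Bifidobacterium	time_point	3_months	24	21
Enterococcus_faecalis	delivery_mode	vaginal	3	0
Enterococcus_faecalis	delivery_mode	elective_CS	2	2
Enterococcus_faecalis	delivery_mode	emergency_CS	4	2
Enterococcus_faecalis	ip_antibiotics	unexposed	2	0
Enterococcus_faecalis	ip_antibiotics	exposed	7	4
Enterococcus_faecalis	time_point	10_days	16	8
Enterococcus_faecalis	time_point	3_months	11	7
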