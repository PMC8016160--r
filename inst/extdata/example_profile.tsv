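taxon_id	name	rank	reads	unique_kmers	marker_coverage	dup
1001	Cutibacterium acnes	species	5000	14500	0.0725	1.05
1002	Staphylococcus epidermidis	species	3000	8700	0.0435	1.03
1003	Micrococcus luteus	species	2000	5800	0.029	1.02
1004	Micrococcus	genus	2100	6100	0.0305	1.02
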