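name	rank	psychrophile	radiophile	spore_forming	biofilm_forming	extreme_environment	desiccation_resistant
Geodermatophilus obscurus	species	FALSE	TRUE	TRUE	FALSE	TRUE	TRUE
Ramlibacter tataouinensis	species	FALSE	FALSE	FALSE	FALSE	TRUE	TRUE
Micrococcus luteus	species	FALSE	TRUE	FALSE	TRUE	TRUE	TRUE
Streptococcus thermophilus	species	FALSE	FALSE	FALSE	TRUE	TRUE	FALSE
Pseudomonas alcaliphila	species	FALSE	FALSE	FALSE	TRUE	TRUE	FALSE
Pseudomonas fragi	species	TRUE	FALSE	FALSE	TRUE	TRUE	FALSE
Deinococcus radiodurans	species	FALSE	TRUE	FALSE	TRUE	TRUE	TRUE
Bacillus subtilis	species	FALSE	FALSE	TRUE	TRUE	FALSE	TRUE
Bacillus pumilus	species	FALSE	TRUE	TRUE	TRUE	TRUE	TRUE
Amycolatopsis methanolica	species	FALSE	FALSE	TRUE	FALSE	TRUE	FALSE
Actinoplanes friuliensis	species	FALSE	FALSE	TRUE	FALSE	FALSE	FALSE
Cutibacterium acnes	species	FALSE	FALSE	FALSE	TRUE	FALSE	FALSE
Staphylococcus epidermidis	species	FALSE	FALSE	FALSE	TRUE	FALSE	TRUE
Staphylococcus aureus	species	FALSE	FALSE	FALSE	TRUE	FALSE	TRUE
Acinetobacter johnsonii	species	FALSE	FALSE	FALSE	TRUE	FALSE	TRUE
Moraxella osloensis	species	FALSE	FALSE	FALSE	TRUE	FALSE	FALSE
Paracoccus yeei	species	FALSE	FALSE	FALSE	FALSE	TRUE	FALSE
Curtobacterium flaccumfaciens	species	FALSE	FALSE	FALSE	FALSE	FALSE	TRUE
Sphingomonas paucimobilis	species	FALSE	FALSE	FALSE	TRUE	FALSE	FALSE
Kocuria rhizophila	species	TRUE	TRUE	FALSE	FALSE	TRUE	TRUE
Kocuria rosea	species	TRUE	TRUE	FALSE	FALSE	TRUE	FALSE
Flavobacterium psychrophilum	species	TRUE	FALSE	FALSE	TRUE	TRUE	FALSE
Methylobacterium radiotolerans	species	FALSE	TRUE	FALSE	FALSE	TRUE	FALSE
Brevundimonas diminuta	species	FALSE	TRUE	FALSE	FALSE	TRUE	FALSE
Stenotrophomonas maltophilia	species	TRUE	FALSE	FALSE	TRUE	FALSE	FALSE
Flavobacterium	genus	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE
Kocuria	genus	TRUE	TRUE	FALSE	FALSE	TRUE	FALSE
Pseudomonas	genus	TRUE	FALSE	FALSE	TRUE	FALSE	FALSE
Stenotrophomonas	genus	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE
Methylobacterium	genus	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE
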