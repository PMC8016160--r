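category	pattern	match_mode
dna_repair	recA	exact_symbol
dna_repair	recB	exact_symbol
dna_repair	uvrA	exact_symbol
dna_repair	uvrB	exact_symbol
dna_repair	mutS	exact_symbol
dna_repair	mutL	exact_symbol
dna_repair	radA	exact_symbol
dna_repair	DNA repair	substring_product
dna_repair	excinuclease	substring_product
dna_repair	photolyase	substring_product
chemotaxis_motility	cheA	exact_symbol
chemotaxis_motility	cheY	exact_symbol
chemotaxis_motility	flgB	exact_symbol
chemotaxis_motility	fliC	exact_symbol
chemotaxis_motility	motA	exact_symbol
chemotaxis_motility	chemotaxis	substring_product
chemotaxis_motility	flagellar	substring_product
biocide_resistance	qacA	exact_symbol
biocide_resistance	qacE	exact_symbol
biocide_resistance	sugE	exact_symbol
biocide_resistance	emrE	exact_symbol
biocide_resistance	quaternary ammonium	substring_product
biocide_resistance	multidrug efflux	substring_product
biocide_resistance	biocide	substring_product
sporulation	spo0A	exact_symbol
sporulation	spoIIE	exact_symbol
sporulation	sspA	exact_symbol
sporulation	cotA	exact_symbol
sporulation	sporulation	substring_product
sporulation	spore coat	substring_product
antimicrobial_resistance	blaZ	exact_symbol
antimicrobial_resistance	tetM	exact_symbol
antimicrobial_resistance	ermC	exact_symbol
antimicrobial_resistance	vanA	exact_symbol
antimicrobial_resistance	beta-lactamase	substring_product
antimicrobial_resistance	aminoglycoside	substring_product
antimicrobial_resistance	antibiotic resistance	substring_product
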