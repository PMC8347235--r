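# Curated subset of widely used PAINS (pan-assay interference) substructure
# alerts, expressed as OpenBabel-compatible SMARTS. This is a hand-picked
# subset covering the most frequently matched alert classes, not the full
# published catalogue; the file format (id<TAB>smarts<TAB>description) is
# user-overridable via the catalogue argument of pains_flag().
id	smarts	description
quinone_A	O=C1C=CC(=O)C=C1	para-quinone
quinone_B	O=C1C(=O)C=CC=C1	ortho-quinone
catechol_A	c1cc(O)c(O)cc1	catechol (redox cycling, chelation)
hydroquinone_A	Oc1ccc(O)cc1	hydroquinone
rhodanine_A	S=C1NC(=O)CS1	rhodanine core
thiazolidinone_A	O=C1CSC(=N)N1	2-imino-thiazolidin-4-one
ene_rhodanine_A	S=C1NC(=O)C(=Cc2ccccc2)S1	benzylidene rhodanine
barbiturate_A	O=C1NC(=O)NC(=O)C1	barbiturate
hydroxyphenyl_hydrazone_A	Oc1ccccc1C=NN	2-hydroxyphenyl hydrazone
azo_A	cN=Nc	aryl azo
alkylidene_barbiturate_A	O=C1NC(=O)NC(=O)C1=C	alkylidene barbiturate
isothiazolone_A	O=C1C=CSN1	isothiazolone
mannich_A	Oc1ccc(CN)cc1O	phenolic Mannich base
curcumin_A	C(=O)CC(=O)C=C	beta-diketone enone
enone_A	O=C(C=Cc1ccccc1)c1ccccc1	chalcone
phenol_sulfonamide_A	Oc1ccccc1S(=O)(=O)N	2-hydroxyphenyl sulfonamide
thiourea_A	NC(=S)N	thiourea
imine_A	C=Nc1ccc(O)cc1	para-hydroxy aryl imine
nitroso_A	O=Nc	aryl nitroso
diazonium_A	[N+]#N	diazonium
michael_acceptor_cyano_A	N#CC=CC#N	bis-cyano Michael acceptor
squarate_A	O=C1C(=O)C(=O)C1	cyclobutanetrione
maleimide_A	O=C1C=CC(=O)N1	maleimide
anhydride_A	O=C1OC(=O)C=C1	maleic anhydride
polyene_A	C=CC=CC=CC=C	extended polyene
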