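molecule_a	molecule_b	label
Linoleic acid	Alpha-linolenic acid	FADS2
Alpha-linolenic acid	Stearidonic acid	FADS2
Stearidonic acid	Eicosapentaenoic acid	ELOVL5/FADS1
Eicosapentaenoic acid	Docosapentaenoic acid	ELOVL2
Docosapentaenoic acid	Docosahexaenoic acid	ELOVL2/FADS2
Cholic acid	Taurocholic acid	BAAT
Cholic acid	Cholic acid glycine	BAAT
Taurocholic acid	Taurodeoxycholic acid	bacterial 7a-dehydroxylation
Cholic acid glycine	Deoxycholic acid glycine	bacterial 7a-dehydroxylation
Chenodeoxycholic acid	Lithocholic acid glycine	BAAT/bacterial
Chenodeoxycholic acid	Taurochenodeoxycholic acid	BAAT
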