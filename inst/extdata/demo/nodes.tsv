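id	name	category	equivalent_identifiers
CHEBI:46195	acetaminophen	biolink:SmallMoleculeDrug	DRUGBANK:DB00316
UniProtKB:P23219	PTGS1	biolink:Protein
UniProtKB:P35354	PTGS2	biolink:Protein
MONDO:0005301	pain disorder (demo)	biolink:Disease
MONDO:0100195	acute pain (demo)	biolink:Disease
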