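id	subject	predicate	object	primary_knowledge_source	publications
e1	CHEBI:46195	biolink:physically_interacts_with	UniProtKB:P23219	infores:demo	PMID:1|PMID:2
e2	UniProtKB:P35354	biolink:physically_interacts_with	CHEBI:46195	infores:demo
e3	CHEBI:46195	biolink:treats	MONDO:0005301	infores:demo	PMID:3
e4	MONDO:0100195	biolink:subclass_of	MONDO:0005301	infores:demo
e5	CHEBI:46195	biolink:treats	MONDO:0100195	infores:demo
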