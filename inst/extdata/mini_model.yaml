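# Mini semantic model: a small Biolink-style hierarchy with enough structure
# to exercise hierarchy expansion, symmetry, inverse pairs and canonical
# direction. Names may be written bare or with a "biolink:" prefix.
categories:
  NamedThing: {}
  BiologicalEntity:
    parents: [NamedThing]
  ChemicalEntity:
    parents: [NamedThing]
  Drug:
    parents: [ChemicalEntity]
  Metabolite:
    parents: [ChemicalEntity]
  SmallMoleculeDrug:
    parents: [Drug]
  Gene:
    parents: [BiologicalEntity]
  Protein:
    parents: [BiologicalEntity]
  Disease:
    parents: [BiologicalEntity]
  PhenotypicFeature:
    parents: [BiologicalEntity]
  AnatomicalEntity:
    parents: [BiologicalEntity]
  Pathway:
    parents: [BiologicalEntity]

predicates:
  related_to:
    symmetric: true
  interacts_with:
    parents: [related_to]
    symmetric: true
  physically_interacts_with:
    parents: [interacts_with]
    symmetric: true
  associated_with:
    parents: [related_to]
    symmetric: true
  affects:
    parents: [related_to]
    canonical: true
    inverse: affected_by
  affected_by:
    parents: [related_to]
    inverse: affects
  treats:
    parents: [affects]
    canonical: true
    inverse: treated_by
  treated_by:
    parents: [affected_by]
    inverse: treats
  causes:
    parents: [affects]
    canonical: true
    inverse: caused_by
  caused_by:
    parents: [affected_by]
    inverse: causes
  regulates:
    parents: [affects]
    canonical: true
    inverse: regulated_by
  regulated_by:
    parents: [affected_by]
    inverse: regulates
  subclass_of:
    parents: [related_to]
    canonical: true
    inverse: superclass_of
  superclass_of:
    parents: [related_to]
    inverse: subclass_of
  participates_in:
    parents: [related_to]

category_prefixes:
  ChemicalEntity: [CHEBI, DRUGBANK]
  Drug: [DRUGBANK, CHEBI]
  SmallMoleculeDrug: [DRUGBANK, CHEBI]
  Metabolite: [CHEBI]
  Gene: [NCBIGene]
  Protein: [UniProtKB]
  Disease: [MONDO, DOID]
  PhenotypicFeature: [HP]
  AnatomicalEntity: [UBERON]
  Pathway: [REACT]
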