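{
  "nodes_file": "nodes.tsv",
  "edges_file": "edges.tsv",
  "endpoint_name": "demo",
  "semantic_model": "../mini_model.yaml",
  "canonicalize": true,
  "preferred_prefix_order": ["CHEBI", "DRUGBANK", "UniProtKB", "MONDO"],
  "trapi_attribute_map": {
    "publications": {
      "attribute_type_id": "biolink:publications",
      "value_type": "linkml:Uriorcurie"
    }
  }
}
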