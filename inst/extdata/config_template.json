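{
  "_comment": [
    "Template service configuration: one file per knowledge graph.",
    "nodes_file / edges_file: local paths (relative to this file) or public",
    "  http(s) URLs of the KGX nodes and edges files (TSV or JSON Lines).",
    "endpoint_name: URL path segment this KG is served under.",
    "semantic_model: schema file with category/predicate hierarchies and",
    "  per-predicate symmetric / inverse / canonical flags.",
    "canonicalize: merge equivalent concept nodes at build time.",
    "trapi_attribute_map: edge/node property -> TRAPI attribute descriptor;",
    "  unmapped properties are emitted with the raw property name.",
    "subclass_sources: optional extra KGX edges files whose subclass_of",
    "  edges feed the transitive subclass closure.",
    "preferred_prefix_order: CURIE prefix priority for picking cluster",
    "  representatives.",
    "resolver_stub: optional JSON file backing the offline id resolver.",
    "rebuild_token_hash: sha-256 hex of the token accepted by POST /rebuild;",
    "  omit to disable remote rebuilds."
  ],
  "nodes_file": "nodes.tsv",
  "edges_file": "edges.tsv",
  "endpoint_name": "mykg",
  "semantic_model": "model.yaml",
  "canonicalize": true,
  "list_delimiter": "|",
  "equivalent_identifiers_property": "equivalent_identifiers",
  "preferred_prefix_order": ["CHEBI", "DRUGBANK", "UniProtKB", "MONDO"],
  "trapi_attribute_map": {
    "publications": {
      "attribute_type_id": "biolink:publications",
      "value_type": "linkml:Uriorcurie"
    },
    "knowledge_level": {
      "attribute_type_id": "biolink:knowledge_level"
    }
  },
  "subclass_predicates": ["subclass_of"],
  "subclass_sources": [],
  "rebuild_token_hash": null
}
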