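Package: onehop
Title: In-Memory Biolink Knowledge Graph Engine for One-Hop TRAPI Queries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Loads Biolink-style knowledge graphs from KGX flat files (TSV or
    JSON Lines), optionally canonicalizes equivalent concept nodes, and builds
    an in-memory adjacency index with semantic reasoning (category and
    predicate hierarchy expansion, predicate symmetry and canonical direction,
    concept equivalence, transitive subclass chaining) encoded at build time
    for constant-time lookup. Answers one-hop TRAPI-shaped pattern-matching
    queries, generates a TRAPI meta knowledge graph with exemplar test
    triples, persists indexes to disk, and exposes everything as a
    multiplexed JSON web API with rebuild support. Includes a synthetic
    knowledge-graph generator and an independent brute-force query oracle for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    digest,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    httpuv,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
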