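# onehop

An in-memory engine for serving Biolink-style biomedical knowledge graphs as
TRAPI-compliant one-hop query APIs, written in R.

Biomedical knowledge graphs (drug–protein interactions, disease–gene
associations, clinical-trial evidence, ...) are usually distributed as flat
KGX files, while the reasoning systems that consume them expect a running web
service that answers *one-hop* pattern-matching queries — two query nodes
joined by one query edge, e.g. *acetaminophen —interacts_with→ Protein?* —
in the standardized TRAPI JSON format. Standing such a service up is more
than a database import: answers must also respect the semantic layer.
`onehop` packages the whole pipeline: loading, entity resolution, semantic
indexing, query answering, meta-knowledge-graph generation, persistence, and
a multiplexed JSON API.

## What the engine computes

Given a knowledge graph *G* and a semantic model (category and predicate
DAGs plus per-predicate `symmetric` / `inverse` / `canonical` flags), a
one-hop answer must include every edge that satisfies the query **not only
directly** but under five reasoning expansions:

1. **Hierarchy** — a query predicate or category also matches all of its
   descendants (`interacts_with` matches `physically_interacts_with`;
   `ChemicalEntity` matches `Drug`).
2. **Symmetry** — a symmetric edge is retrievable from either endpoint.
3. **Canonical direction** — each inverse predicate pair is stored once
   under its canonical member (`treated_by(x,y)` is stored as
   `treats(y,x)` with the flip recorded); queries in either form answer
   against the same storage.
4. **Concept equivalence** — CURIEs naming the same concept are clustered
   (union–find over `equivalent_identifiers`, or an offline resolver stub)
   and optionally merged into one canonical node per cluster.
5. **Subclass chaining** — a query pinned to concept X also answers with
   transitive `subclass_of` descendants of X, flagged via `query_id`.

The core data structure is a nested adjacency index,

```
node → neighbor-category → predicate → direction → {(neighbor, edge)}
```

with all hierarchy/symmetry/canonicity expansion baked in **at build time**
(each edge is registered under every ancestor of its canonical predicate and
every ancestor category of its endpoints), so query terms are looked up
verbatim with no ontology walk at query time. The trade-off is deliberate:
memory for speed — per-query work is then proportional to the answer size.
Correctness of the whole reasoning stack is defined and checked against an
independent brute-force oracle that re-derives every expansion naively per
edge.

## Worked example

The package ships a five-node demo KG (acetaminophen, two COX proteins, two
demo disease concepts) with a mini Biolink-style model:

```r
library(onehop)
cfg   <- load_configs(system.file("extdata", "demo", package = "onehop"))
state <- build_service(cfg)
print(state)
#> <service_state> 1 endpoint(s), code version 0.1.0
#>   /demo: ok

body <- jsonlite::toJSON(list(message = list(query_graph = list(
  nodes = list(n0 = list(ids = list("DRUGBANK:DB00316")),
               n1 = list(categories = list("biolink:Protein"))),
  edges = list(e0 = list(subject = "n0", object = "n1",
                         predicates = list("biolink:interacts_with")))))),
  auto_unbox = TRUE)
resp <- handle_request(state, "/demo/query", "POST", body)
resp$status
#> [1] 200
```

The two results bind the drug to both proteins:

```
CHEBI:46195 (query_id DRUGBANK:DB00316) -> UniProtKB:P23219 via e1
CHEBI:46195 (query_id DRUGBANK:DB00316) -> UniProtKB:P35354 via e2
```

Every reasoning step is visible here: the query pinned `DRUGBANK:DB00316`,
which resolved through its equivalence cluster to the canonical node
`CHEBI:46195` (hence the `query_id` annotation); the query predicate
`interacts_with` matched stored `physically_interacts_with` edges through
the hierarchy; and edge `e2` was written in the KGX file as *protein →
drug* but is found from the drug side because the predicate is symmetric.
`GET /demo/meta_knowledge_graph` summarizes the same KG as 4 meta-edges
with exemplar test triples at `GET /demo/sri_test_triples`.

A command-line front end (`exec/onehop`) wraps the same functions:
`onehop serve --config-dir DIR [--port N]`, `onehop build`, `onehop query`
(one-shot, no server), and `onehop synth` for generating synthetic KGs. A
minimal container recipe is provided under `inst/docker/`.

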