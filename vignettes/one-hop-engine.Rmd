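---
title: "Serving Biolink knowledge graphs as one-hop TRAPI APIs: methods and design"
author: "onehop authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serving Biolink knowledge graphs as one-hop TRAPI APIs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Reasoning systems over biomedical knowledge graphs consume them through
standardized web APIs that answer *one-hop* queries: two query nodes joined
by one query edge, with nodes constrained by identifier (CURIE) and
category, and edges by predicate and attributes. A correct answer set is
defined not by literal edge matching but by the semantic layer: type
hierarchies, predicate symmetry and canonical direction, concept
equivalence, and transitive subclass relationships all widen the answer.
`onehop` implements the full pipeline from KGX flat files to such an API,
with every reasoning expansion resolved **at index-build time** so that
query-time work reduces to key lookups plus answer assembly.

This vignette records the model, its assumptions, the tunable parameters,
the numerical and design choices made where the design was genuinely open,
what the synthetic validation does and does not show, and known limitations.

## The semantic model

The reasoning substrate is a pair of DAGs (categories, predicates) with
per-predicate flags:

* `symmetric` — `p(a,b) ⇒ p(b,a)`;
* `inverse` — a reciprocal pair `(p, q)` with `p(a,b) ⇔ q(b,a)`, exactly
  one member marked `canonical`;
* `canonical` — the storage direction of an inverse pair; predicates with
  no inverse are canonical by definition, and symmetric predicates never
  have an inverse.

The schema dialect is a flat YAML/JSON mapping rather than a full LinkML
release: only the hierarchy/symmetry/canonicity facts matter to the engine,
and a real Biolink release maps onto the dialect by exporting each class
and slot's `is_a`/mixin parents plus the three slot annotations. Multiple
parents are allowed (Biolink has mixins); descendant sets are computed on
the DAG. Names are compared case-sensitively after stripping an optional
`biolink:` prefix and re-emitted prefixed in TRAPI output. Validation is
strict — dangling parents, cycles, non-reciprocal inverses and ambiguous
canonicity are fatal — because every downstream structure trusts these
facts. Inclusive descendant and ancestor closures of every name are
memoized at load time.

### Hierarchy semantics on the canonical form

One semantic choice deserves emphasis: an edge implies the ancestor set of
its **canonical** predicate. A `treated_by` edge is first flipped to
`treats`, and then inherits `treats`'s ancestors; any parents declared on
`treated_by` itself are ignored. This keeps storage and query expansion
coherent (both sides of an inverse pair reason over one hierarchy chain)
and matches how canonical-direction modeling is used in practice, where
hierarchy is maintained over canonical predicates. The brute-force oracle
implements the same documented rule with independent code, so the test
suite would catch any divergence between the two readings.

## Graph loading

KGX comes in two dialects (TSV and JSON Lines); both are supported, with
`auto` sniffing by extension then first byte. Loading policy, chosen for
total builds over imperfect real-world exports:

* dangling edges (endpoint absent from the nodes file) are **dropped and
  counted**, not fatal;
* duplicate node ids: last occurrence wins, counted;
* duplicate edge ids: deterministically re-suffixed (`#2`, `#3`, ...);
* missing edge ids: synthesized as a stable hash of
  subject/predicate/object/primary knowledge source;
* nodes listing no category receive the model's root category, keeping the
  index total;
* the TSV multi-value delimiter defaults to `|` and is configurable per KG,
  as is the name of the equivalence property (`equivalent_identifiers` by
  default).

Nodes and edges are stored sorted by id, which makes loads deterministic
and write→read round trips exact. URL sources are fetched once into a cache
keyed by a hash of the URL.

## Entity resolution and canonicalization

Equivalence clusters are built by union–find (path compression,
deterministic smaller-string root, sorted iteration) over each node's
`{id} ∪ equivalent_identifiers`. Nodes lacking the property can fall back
to a pluggable resolver honoring a batch contract (every queried CURIE gets
an entry); the shipped implementation is a file-backed offline stub, and a
failing resolver degrades to singleton clusters with a warning so builds
never require network access. Cluster representatives are chosen by a
configurable CURIE-prefix priority, with ties and unlisted prefixes broken
by lexicographic order on the full CURIE string — a textual, not numeric,
order (`"X:10"` precedes `"X:2"`), chosen for determinism without parsing
local identifier schemes.

Optional canonicalization merges each cluster into one node keyed by the
representative: categories are unioned in first-seen order (representative
first), the representative's name and scalar properties win, conflicting
scalars are stashed losslessly under `_merged_values`, and
`equivalent_identifiers` becomes the set of other members. Edges re-point
to representatives; self-loops created by merging are kept (dropping them
would silently discard assertions); edges made identical by re-pointing
(same subject, object, predicate and primary knowledge source) merge with
property union. The operation is idempotent, which the tests check both on
fixtures and seeded random graphs.

A consequence worth knowing: when a graph is *not* canonicalized, a query
pinned to a non-representative member resolves to the cluster
representative (plus its subclass descendants). On the canonicalized
deployment — the intended configuration whenever equivalence data is
present — only representatives exist as nodes, so nothing is lost; on a raw
graph, member-local edges are reachable by pinning the member's
representative. The demo configuration therefore enables `canonicalize`.

## The adjacency index

The core structure maps

```
node → neighbor-category → predicate → direction → {(neighbor, edge)}
```

realized as a radix-keyed table so a lookup is a binary-search join, plus
hashed per-id views of the node and edge stores so response assembly is
O(answer size) rather than O(graph size). At build time each edge is:

1. put into canonical form (flip recorded on the stored edge);
2. registered under **every inclusive ancestor** of its canonical
   predicate;
3. under each such key predicate, registered from both endpoints in
   direction `out` if that key predicate is symmetric, otherwise subject →
   `out`, object → `in`;
4. keyed by **all categories of the neighbor plus their ancestors**.

Storing under ancestors (rather than expanding query terms to descendants
at query time) is the engine's central trade: memory for constant-time
lookup. Edges whose predicate is unknown to the model are indexed under the
root predicate only, with a counted warning — a total build beats a fatal
one on imperfect inputs, and the root key keeps them findable by
unconstrained queries.

Subclass closure is computed separately by breadth-first reachability over
reversed `subclass_of` edges (predicate set configurable; an external KGX
edge file can be unioned in). Chaining is unbounded by default — that is
what "transitive" means — with a `max_depth` guard available for
pathological inputs. Cycles are tolerated: members of a cycle reach each
other but are never listed as their own descendants. Subclass edges remain
ordinary queryable edges.

Snapshots persist all structures to a versioned directory (JSON manifest
with a format-version integer and the semantic-model checksum; JSON Lines
stores; TSV tables), written in sorted order so snapshots of identical
inputs are identical. Loading distinguishes missing, corrupt and
version-mismatched snapshots, and a model-checksum mismatch triggers a
rebuild rather than serving stale reasoning.

## Query answering

`validate_query` enforces the one-hop contract: exactly two query nodes and
one query edge, at least one node pinned to ids, all names known to the
model, operators from `{==, >, <, matches}`. Fully unpinned queries are
rejected — they enumerate the graph rather than look anything up. On a
pinned query node, ids take precedence and categories are ignored; a node
is constrained by identifier *or* by type, with identifiers strictly
stronger.

`answer_query` then: picks the pinned node (fewer resolved ids wins when
both are pinned; ties go to the query-edge subject); resolves ids through
equivalence and subclass reasoning; expands query predicates to descendants
and maps each through its canonical form, grouping lookups by the implied
direction (symmetric keys are direction-free) — this query-side descent is
needed because a descendant of a non-canonical query predicate can
canonicalize outside the query predicate's own storage key; passes the
opposite node's categories verbatim (the index already contains ancestor
keys); filters candidates by attribute constraints; and assembles the
response. Answers reached through an equivalent or subclass identifier
carry `query_id` on their node binding — no synthetic support-graph edges
are fabricated, a minimal reading documented here as a divergence risk
against consumers that expect auxiliary graphs.

Attribute constraints are a conjunction; `==` is membership when either
side is multi-valued, `matches` is a regular-expression search, `>`/`<`
compare numerically and raise a typed error (mapped to HTTP 400) on
non-numeric operands, a missing property is unsatisfied before negation,
and `not` inverts a single constraint. Constraint ids are translated to
edge properties through the configured TRAPI attribute map, falling back to
the raw property name.

Responses use the TRAPI 1.4+ results/analyses/edge_bindings nesting with
exactly one analysis per result; results are unique per (subject binding,
object binding) pair with all supporting edges bound in one analysis.
Deterministic output ordering (results by binding pair, knowledge-graph
keys sorted) makes byte-level response comparison meaningful, which the
concurrency and persistence tests rely on.

## Meta-KG and test triples

The meta knowledge graph is computed from **stored canonical, unexpanded**
edges — expanded index entries would inflate counts by hierarchy depth.
Each edge contributes under the most specific category of each endpoint,
taken as the first listed category per KGX convention; with that policy the
counts sum exactly to the stored edge count. An `all`-categories policy is
available and documented as relaxing that identity. Per-category
`id_prefixes` use the model's declared lists when present, else observed
CURIE prefixes ordered by frequency then name. One exemplar test triple per
meta-edge is selected by ranking edge ids under a seed-keyed hash — fully
deterministic per seed, different seeds sample different exemplars.

## Service layer

Each KG is one JSON config file; multiplexing is one file per KG, each
served under its `endpoint_name`. The routing core is a pure function from
(state, route, method, body, headers) to an HTTP-shaped response, so the
whole route table — query, meta-KG, test triples, code version, log tail,
healthcheck, rebuild — is tested without sockets; `serve_http()` is a thin
runner over it (via `httpuv`, an optional dependency). A failed endpoint
build is isolated: the healthcheck reports it while other endpoints serve.
The log endpoint returns the tail (default 500 lines) of a bounded
in-memory structured log, never raw files.

`/rebuild` is authenticated by comparing the sha-256 of a presented token
against the configured hash over fixed-length digests. The rebuild runs the
full pipeline into a fresh endpoint table and swaps it into the state
environment in a single assignment, so a request observes either the old or
the new state in its entirety; rebuild requests during a rebuild get 409.
In this single-process R implementation the build runs synchronously before
the 202 is returned — the atomic-swap and never-half-built contracts are
what the tests verify; a forked background build would change latency, not
observable semantics.

## Synthetic validation: what it shows

The generator (`synth_spec` / `generate_kg`) emits random category and
predicate DAGs of configurable depth, uniform random edges, planted
equivalence clusters (size 2–3) and planted `subclass_of` chains, in both
KGX dialects plus the matching schema and a ground-truth JSON. One
pseudo-random sub-stream per purpose is derived from the single seed, so
adding a generation phase does not perturb earlier draws; a fixed seed is
byte-reproducible. Default condition parameters — 50 nodes, 200 edges,
hierarchy depth 2, 25 % symmetric predicates, 25 % inverse pairs, 10 %
of nodes in equivalence clusters, two subclass chains of length 3 — were
chosen once as a small graph that still exercises every reasoning feature
simultaneously: deep enough hierarchies to make descendant matching
non-trivial, enough inverse pairs that canonical flips occur in most
graphs, clusters and chains frequent enough that equivalence- and
subclass-derived answers appear routinely.

Correctness is defined by `brute_force_answer`, an oracle that shares input
data structures but no expansion code with the engine: per edge and per
query it re-derives descendant sets by recursive parent walks, canonical
forms from the raw flags, resolution sets by naive reachability, category
membership by ancestor walks, and constraints by its own evaluator. The
acceptance suite checks exact triple-set equality over 50 seeded graphs ×
10 random queries, alternating canonicalized and raw deployments, alongside
a hand-traced battery with one fixture per reasoning feature (including a
subclass cycle).

What this does **not** show: realistic degree distributions, real
ontologies (the generated DAGs are shallow and regular), qualifier
semantics, attribute-heavy edges, or behavior at the scale of
multi-million-edge production graphs. The scaling study covers the
asymptotic shape — answers of 10¹–10⁵ edges on star graphs, median
per-call response time (small answers timed in batches so measurements sit
well above timer granularity), log-log regression slope required to lie in
[0.8, 1.2] — but absolute times are hardware-specific, and graphs beyond
~10⁵ answer edges per query are untested.

## Numerical and operational choices

* Lexicographic (C-locale radix) ordering everywhere a tie must break:
  representative selection, stored node/edge order, response ordering.
* Seeds derived from a single user seed stay below 2³¹ (R integers are
  32-bit); derived seeds are taken modulo a large prime.
* Edge-id synthesis and test-triple selection use sha-1 prefixes — a
  stable, platform-independent deterministic hash, not a security boundary;
  the rebuild token uses sha-256.
* Degenerate inputs: empty graphs, header-only files, empty predicate or
  category sets (explicit empty set → empty answer; absent → "all"),
  unknown pinned ids (resolve to nothing, not an error), unknown nodes in
  lookups (empty result) are all total paths, tested.
* The per-endpoint build pipeline is read → equivalence map → optional
  canonicalize → subclass closure → index → meta-KG → test triples →
  snapshot; the equivalence map is always built on the *raw* graph so
  member CURIEs keep resolving after canonicalization.

## Known limitations

* One-hop only: no multi-hop planning, no qualifier constraints, no
  asynchronous TRAPI operations, no result scoring (downstream reasoning
  agents rank).
* The resolver is an offline stub contract; live node-normalization
  services are out of scope by design.
* Build-time ancestor expansion multiplies index rows by hierarchy depth —
  the deliberate memory-for-speed trade; very deep hierarchies over very
  large graphs would need the memory budget checked first.
* R's single-process service model relies on shared read-only state for
  concurrency; the contract tests enforce no in-request mutation, but true
  parallel serving requires an external process manager.
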