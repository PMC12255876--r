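# Shared fixtures: all test data is built in code or loaded from the tiny
# text files shipped under extdata.

mini_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- load_semantic_model(
        system.file("extdata", "mini_model.yaml", package = "onehop"))
    }
    cache
  }
})

# Construct an in-memory kg_graph directly (no file round trip).
make_node <- function(id, categories, name = id, eq = character(0), props = list()) {
  list(id = id, name = name, categories = categories,
       equivalent_identifiers = eq, properties = props)
}

make_edge <- function(id, subject, predicate, object, props = list()) {
  if (is.null(props$primary_knowledge_source)) {
    props$primary_knowledge_source <- "infores:test"
  }
  list(id = id, subject = subject, object = object, predicate = predicate,
       properties = props)
}

make_graph <- function(nodes, edges) {
  nodes <- setNames(nodes, vapply(nodes, `[[`, character(1), "id"))
  edges <- setNames(edges, vapply(edges, `[[`, character(1), "id"))
  structure(list(
    nodes = nodes[order(names(nodes), method = "radix")],
    edges = edges[order(names(edges), method = "radix")],
    provenance = list(equivalent_identifiers_property = "equivalent_identifiers",
                      warnings = list(duplicate_nodes = 0L, duplicate_edge_ids = 0L,
                                      dangling_edges = 0L))
  ), class = "kg_graph")
}

# Write a small KGX TSV pair from row strings (header included by caller).
write_tsv_fixture <- function(dir, node_lines, edge_lines) {
  np <- file.path(dir, "nodes.tsv"); ep <- file.path(dir, "edges.tsv")
  writeLines(node_lines, np); writeLines(edge_lines, ep)
  list(nodes = np, edges = ep)
}

# Build everything the query engine needs from a graph + model.
build_all <- function(graph, model, canonicalize = FALSE,
                      prefix_priority = character(0), external_subclass = NULL) {
  eqmap <- build_equivalence_map(graph, prefix_priority = prefix_priority)
  g2 <- if (canonicalize) canonicalize_graph(graph, eqmap) else graph
  subclass <- build_subclass_closure(g2, external_edges = external_subclass)
  index <- build_index(g2, model)
  list(graph = g2, eqmap = eqmap, subclass = subclass, index = index)
}

# Subclass edge list of a graph, as the oracle consumes it.
subclass_edge_list <- function(graph, predicates = "subclass_of") {
  rows <- Filter(function(e) e$predicate %in% predicates, graph$edges)
  data.frame(
    subject = vapply(rows, `[[`, character(1), "subject"),
    predicate = vapply(rows, `[[`, character(1), "predicate"),
    object = vapply(rows, `[[`, character(1), "object"),
    stringsAsFactors = FALSE, row.names = NULL)
}

# One-hop query-graph constructor.
qg <- function(subj = list(), obj = list(), predicates = NULL, constraints = NULL,
               subj_key = "n0", obj_key = "n1") {
  qe <- list(subject = subj_key, object = obj_key)
  if (!is.null(predicates)) qe$predicates <- predicates
  if (!is.null(constraints)) qe$attribute_constraints <- constraints
  list(nodes = setNames(list(subj, obj), c(subj_key, obj_key)),
       edges = list(e0 = qe))
}

# Random one-hop query over a generated graph, exercising equivalence,
# hierarchy and subclass answers. Pinned qnodes carry ids only.
random_query <- function(graph, model) {
  ids <- names(graph$nodes)
  pick_side <- function() list(ids = sample(ids, sample(1:2, 1L)))
  cat_side <- function() {
    if (stats::runif(1) < 0.5) list() else
      list(categories = sample(names(model$categories), 1L))
  }
  preds <- if (stats::runif(1) < 0.2) NULL else
    sample(names(model$predicates), sample(1:2, 1L))
  both <- stats::runif(1) < 0.25
  pin_subject <- stats::runif(1) < 0.5
  if (both) {
    qg(subj = pick_side(), obj = pick_side(), predicates = preds)
  } else if (pin_subject) {
    qg(subj = pick_side(), obj = cat_side(), predicates = preds)
  } else {
    qg(subj = cat_side(), obj = pick_side(), predicates = preds)
  }
}

# Engine answer as a sorted triple table, for oracle comparison.
engine_triples <- function(qgraph, parts, model) {
  resp <- answer_query(qgraph, parts$index, model, parts$subclass, parts$eqmap)
  response_triples(resp)
}

# Generate a synthetic KG into a temp dir and load the TSV dialect.
synth_graph <- function(seed, n_nodes = 40L, n_edges = 120L, ...) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  res <- generate_kg(synth_spec(n_nodes = n_nodes, n_edges = n_edges,
                                seed = seed, ...), dir)
  model <- load_semantic_model(res$model)
  graph <- read_graph(res$nodes_tsv, res$edges_tsv, root_category = model$root_category)
  list(res = res, model = model, graph = graph, dir = dir)
}
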