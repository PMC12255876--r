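test_that("an empty graph builds an empty index", {
  g <- make_graph(list(), list())
  idx <- build_index(g, mini_model())
  expect_identical(nrow(idx$adj), 0L)
  expect_length(idx$edge_store, 0L)
  expect_identical(nrow(lookup_neighbors(idx, "X:1")), 0L)
})

test_that("a symmetric edge is retrievable from both endpoints under ancestors", {
  m <- mini_model()
  g <- make_graph(
    list(make_node("X:A", "Drug"), make_node("X:B", "Protein")),
    list(make_edge("e1", "X:A", "physically_interacts_with", "X:B")))
  idx <- build_index(g, m)

  for (p in c("physically_interacts_with", "interacts_with")) {
    from_a <- lookup_neighbors(idx, "X:A", predicates = p)
    from_b <- lookup_neighbors(idx, "X:B", predicates = p)
    expect_identical(from_a$nbr, "X:B")
    expect_identical(from_b$nbr, "X:A")
    expect_identical(from_a$eid, "e1")
  }
  # symmetric keys live in direction `out` from both endpoints
  expect_identical(nrow(lookup_neighbors(idx, "X:B",
                                         predicates = "interacts_with",
                                         direction = "in")), 0L)
})

test_that("non-canonical predicates are stored flipped in canonical form", {
  m <- mini_model()
  g <- make_graph(
    list(make_node("X:C", "Disease"), make_node("X:D", "Drug")),
    list(make_edge("e1", "X:C", "treated_by", "X:D")))
  idx <- build_index(g, m)
  stored <- idx$edge_store[["e1"]]
  expect_identical(stored$predicate, "treats")
  expect_identical(stored$subject, "X:D")
  expect_identical(stored$object, "X:C")
  expect_true(stored$flipped)
  # retrievable from the drug side outward under treats and its ancestors
  expect_identical(lookup_neighbors(idx, "X:D", predicates = "treats",
                                    direction = "out")$nbr, "X:C")
  expect_identical(lookup_neighbors(idx, "X:C", predicates = "affects",
                                    direction = "in")$nbr, "X:D")
})

test_that("lookup semantics: unknown node, empty sets, category keys", {
  m <- mini_model()
  g <- make_graph(
    list(make_node("X:A", "Drug"), make_node("X:B", "Protein")),
    list(make_edge("e1", "X:A", "physically_interacts_with", "X:B")))
  idx <- build_index(g, m)
  expect_identical(nrow(lookup_neighbors(idx, "X:nope")), 0L)
  expect_identical(nrow(lookup_neighbors(idx, "X:A", predicates = character(0))), 0L)
  expect_identical(nrow(lookup_neighbors(idx, "X:A",
                                         neighbor_categories = character(0))), 0L)
  # ancestor category keys reach the same pair; sibling categories do not
  expect_identical(lookup_neighbors(idx, "X:A",
                                    neighbor_categories = "BiologicalEntity")$nbr, "X:B")
  expect_identical(nrow(lookup_neighbors(idx, "X:A",
                                         neighbor_categories = "Disease")), 0L)
})

test_that("edges with model-unknown predicates index under the root with a warning", {
  m <- mini_model()
  g <- make_graph(
    list(make_node("X:A", "Drug"), make_node("X:B", "Protein")),
    list(make_edge("e1", "X:A", "frobnicates", "X:B")))
  idx <- build_index(g, m)
  expect_identical(idx$build_meta$warnings$unknown_predicate_edges, 1L)
  expect_identical(lookup_neighbors(idx, "X:A", predicates = "related_to")$nbr, "X:B")
  expect_identical(nrow(lookup_neighbors(idx, "X:A", predicates = "treats")), 0L)
})

test_that("expansion soundness holds exhaustively on a fixture index", {
  m <- mini_model()
  sg <- synth_graph(5L, n_nodes = 20L, n_edges = 50L)
  idx <- build_index(sg$graph, sg$model)
  adj <- idx$adj
  present <- unique(paste(adj$node, adj$ncat, adj$pred, adj$eid, sep = "\x1f"))

  # every entry must also appear under each ancestor of its predicate ...
  anc_p <- sg$model$pred_anc[adj$pred]
  need_p <- paste(rep(adj$node, lengths(anc_p)), rep(adj$ncat, lengths(anc_p)),
                  unlist(anc_p, use.names = FALSE), rep(adj$eid, lengths(anc_p)),
                  sep = "\x1f")
  expect_true(all(need_p %in% present))

  # ... and under each ancestor of its neighbor-category key
  anc_c <- sg$model$cat_anc[adj$ncat]
  need_c <- paste(rep(adj$node, lengths(anc_c)), unlist(anc_c, use.names = FALSE),
                  rep(adj$pred, lengths(anc_c)), rep(adj$eid, lengths(anc_c)),
                  sep = "\x1f")
  expect_true(all(need_c %in% present))
})

test_that("subclass closure matches BFS reachability, including cycles", {
  m <- mini_model()
  g <- make_graph(
    list(make_node("X:A", "Disease"), make_node("X:B", "Disease"),
         make_node("X:C", "Disease")),
    list(make_edge("s1", "X:C", "subclass_of", "X:B"),
         make_edge("s2", "X:B", "subclass_of", "X:A")))
  sc <- build_subclass_closure(g)
  expect_setequal(sc$descendants_of[["X:A"]], c("X:B", "X:C"))
  expect_identical(sc$descendants_of[["X:B"]], "X:C")
  expect_null(sc$descendants_of[["X:C"]])

  # 2-cycle: mutual descendants, no self-membership, terminates
  gc <- make_graph(
    list(make_node("X:X", "Disease"), make_node("X:Y", "Disease")),
    list(make_edge("s1", "X:X", "subclass_of", "X:Y"),
         make_edge("s2", "X:Y", "subclass_of", "X:X")))
  scc <- build_subclass_closure(gc)
  expect_identical(scc$descendants_of[["X:X"]], "X:Y")
  expect_identical(scc$descendants_of[["X:Y"]], "X:X")

  # no subclass edges -> empty sets; empty predicate set is a config error
  expect_length(build_subclass_closure(make_graph(list(), list()))$descendants_of, 0L)
  expect_error(build_subclass_closure(g, subclass_predicates = character(0)),
               class = "onehop_config_error")
})

test_that("max_depth truncates the chaining and external edges are unioned", {
  g <- make_graph(
    list(make_node("X:A", "Disease"), make_node("X:B", "Disease"),
         make_node("X:C", "Disease")),
    list(make_edge("s1", "X:C", "subclass_of", "X:B"),
         make_edge("s2", "X:B", "subclass_of", "X:A")))
  sc1 <- build_subclass_closure(g, max_depth = 1L)
  expect_identical(sc1$descendants_of[["X:A"]], "X:B")

  ext <- data.frame(subject = "X:D", predicate = "subclass_of", object = "X:C")
  sc2 <- build_subclass_closure(g, external_edges = ext)
  expect_setequal(sc2$descendants_of[["X:A"]], c("X:B", "X:C", "X:D"))
})

test_that("save/load round-trips are observationally identical", {
  m <- mini_model()
  sg <- synth_graph(9L, n_nodes = 25L, n_edges = 60L,
                    equivalence_cluster_rate = 0.2)
  parts <- build_all(sg$graph, sg$model, canonicalize = TRUE)
  dir <- withr::local_tempdir()
  save_index(parts$index, parts$subclass, parts$eqmap, dir)
  back <- load_index(dir)

  expect_identical(sort(names(back$index$edge_store)),
                   sort(names(parts$index$edge_store)))
  expect_identical(back$eqmap$cluster_of, parts$eqmap$cluster_of)
  for (node in head(names(parts$index$node_store), 10L)) {
    a <- lookup_neighbors(parts$index, node)
    b <- lookup_neighbors(back$index, node)
    expect_identical(a, b)
  }
  withr::with_seed(1L, {
    for (i in 1:10) {
      q <- random_query(sg$graph, sg$model)
      r1 <- response_triples(answer_query(q, parts$index, sg$model,
                                          parts$subclass, parts$eqmap))
      r2 <- response_triples(answer_query(q, back$index, sg$model,
                                          back$subclass, back$eqmap))
      expect_identical(r1, r2)
    }
  })
})

test_that("snapshot loading distinguishes missing, corrupt and version mismatch", {
  dir <- withr::local_tempdir()
  expect_error(load_index(file.path(dir, "absent")), class = "onehop_snapshot_missing")

  g <- make_graph(list(), list())
  idx <- build_index(g, mini_model())
  snap <- file.path(dir, "snap")
  save_index(idx, NULL, NULL, snap)
  back <- load_index(snap)
  expect_length(back$index$edge_store, 0L)

  # corrupt: remove a component
  unlink(file.path(snap, "adjacency.tsv"))
  expect_error(load_index(snap), class = "onehop_snapshot_corrupt")

  # version mismatch
  snap2 <- file.path(dir, "snap2")
  save_index(idx, NULL, NULL, snap2)
  man <- jsonlite::fromJSON(file.path(snap2, "manifest.json"), simplifyVector = FALSE)
  man$format_version <- 99L
  jsonlite::write_json(man, file.path(snap2, "manifest.json"), auto_unbox = TRUE)
  expect_error(load_index(snap2), class = "onehop_snapshot_version")
})
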