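test_that("validate_query enforces the one-hop contract", {
  m <- mini_model()
  good <- qg(subj = list(ids = "X:1"), obj = list(categories = "Protein"),
             predicates = "treats")
  expect_identical(validate_query(good, m), character(0))

  three_nodes <- list(
    nodes = list(n0 = list(ids = "X:1"), n1 = list(), n2 = list()),
    edges = list(e0 = list(subject = "n0", object = "n1"),
                 e1 = list(subject = "n1", object = "n2")))
  expect_match(validate_query(three_nodes, m), "not one-hop")

  expect_match(validate_query(qg(subj = list(ids = "X:1"),
                                 predicates = "frobnicates"), m),
               "frobnicates", all = FALSE)
  expect_match(validate_query(qg(subj = list(ids = "X:1"),
                                 obj = list(categories = "Widget")), m),
               "Widget", all = FALSE)
  expect_match(validate_query(qg(subj = list(), obj = list(categories = "Drug")), m),
               "pinned", all = FALSE)
  bad_con <- qg(subj = list(ids = "X:1"),
                constraints = list(list(id = "publications", operator = "~=")))
  expect_match(validate_query(bad_con, m), "operator", all = FALSE)
})

test_that("resolve_pinned_ids composes equivalence and subclass expansion", {
  m <- mini_model()
  g <- make_graph(
    list(make_node("X:q2", "Disease"), make_node("X:s", "Disease"),
         make_node("X:d", "Drug")),
    list(make_edge("s1", "X:s", "subclass_of", "X:q2")))
  eqmap <- structure(list(
    cluster_of = c(`X:q` = "X:q2", `X:q2` = "X:q2"),
    members_of = list(`X:q2` = c("X:q", "X:q2"))), class = "equivalence_map")
  parts <- build_all(g, m)

  r <- resolve_pinned_ids("X:q", eqmap, parts$subclass, parts$index)
  expect_identical(r, c(`X:q2` = "X:q", `X:s` = "X:q"))
  # plain id present in the graph, nothing to expand
  expect_identical(resolve_pinned_ids("X:d", eqmap, parts$subclass, parts$index),
                   c(`X:d` = "X:d"))
  # absent everywhere -> resolves to nothing
  expect_identical(resolve_pinned_ids("X:gone", eqmap, parts$subclass, parts$index),
                   character(0))
  # first queried id keeps a shared concrete id
  r2 <- resolve_pinned_ids(c("X:q", "X:s"), eqmap, parts$subclass, parts$index)
  expect_identical(r2[["X:s"]], "X:q")
})

test_that("attribute constraints follow membership/regex/numeric semantics", {
  edge <- make_edge("e1", "X:1", "treats", "X:2",
                    props = list(publications = c("PMID:1", "PMID:2"),
                                 score = "0.75",
                                 knowledge_level = "prediction"))
  con <- function(id, op, value, not = FALSE) {
    list(list(id = id, operator = op, value = value, not = not))
  }
  expect_true(apply_attribute_constraints(edge, list()))
  expect_true(apply_attribute_constraints(edge, con("publications", "==", "PMID:2")))
  expect_false(apply_attribute_constraints(edge, con("publications", "==", "PMID:2",
                                                     not = TRUE)))
  expect_false(apply_attribute_constraints(edge, con("publications", "==", "PMID:9")))
  expect_true(apply_attribute_constraints(edge, con("score", ">", 0.5)))
  expect_false(apply_attribute_constraints(edge, con("score", "<", 0.5)))
  expect_true(apply_attribute_constraints(edge, con("knowledge_level", "matches", "^pred")))
  # missing property is unsatisfied before negation
  expect_false(apply_attribute_constraints(edge, con("absent_prop", "==", "x")))
  expect_true(apply_attribute_constraints(edge, con("absent_prop", "==", "x", not = TRUE)))
  # conjunction
  both <- c(con("publications", "==", "PMID:1"), con("score", ">", 0.9))
  expect_false(apply_attribute_constraints(edge, both))
  # constraint ids map through the attribute map
  amap <- list(publications = list(attribute_type_id = "biolink:publications"))
  expect_true(apply_attribute_constraints(
    edge, con("biolink:publications", "==", "PMID:1"), amap))
  expect_error(apply_attribute_constraints(edge, con("knowledge_level", ">", 1)),
               class = "onehop_constraint_error")
})

test_that("answer_query over an empty index returns an empty response", {
  m <- mini_model()
  parts <- build_all(make_graph(list(), list()), m)
  resp <- answer_query(qg(subj = list(ids = "X:1")), parts$index, m,
                       parts$subclass, parts$eqmap)
  expect_length(resp$message$results, 0L)
  expect_length(resp$message$knowledge_graph$edges, 0L)
  expect_identical(resp$status, "Success")
})

test_that("every bound id appears in the knowledge graph and results are sorted", {
  sg <- synth_graph(21L, n_nodes = 40L, n_edges = 150L)
  parts <- build_all(sg$graph, sg$model)
  withr::with_seed(7L, {
    for (i in 1:15) {
      q <- random_query(sg$graph, sg$model)
      resp <- answer_query(q, parts$index, sg$model, parts$subclass, parts$eqmap)
      kg_nodes <- names(resp$message$knowledge_graph$nodes)
      kg_edges <- names(resp$message$knowledge_graph$edges)
      keys <- character(0)
      for (res in resp$message$results) {
        for (nb in unlist(res$node_bindings, recursive = FALSE)) {
          expect_true(nb$id %in% kg_nodes)
        }
        ebs <- res$analyses[[1L]]$edge_bindings[[1L]]
        for (eb in ebs) expect_true(eb$id %in% kg_edges)
        keys <- c(keys, paste(res$node_bindings[[1L]][[1L]]$id,
                              res$node_bindings[[2L]][[1L]]$id))
      }
      expect_false(is.unsorted(keys))
      expect_identical(anyDuplicated(keys), 0L)
      expect_false(is.unsorted(kg_nodes))
      expect_false(is.unsorted(kg_edges))
    }
  })
})

test_that("swapping subject and object of a symmetric-only query preserves triples", {
  sg <- synth_graph(31L, n_nodes = 30L, n_edges = 100L)
  parts <- build_all(sg$graph, sg$model)
  sym_preds <- names(Filter(function(p) p$symmetric, sg$model$predicates))
  pinned <- names(sg$graph$nodes)[5L]
  fwd <- qg(subj = list(ids = pinned), predicates = sym_preds)
  rev <- qg(subj = list(), obj = list(ids = pinned), predicates = sym_preds)
  t_fwd <- engine_triples(fwd, parts, sg$model)
  t_rev <- engine_triples(rev, parts, sg$model)
  # same pairs modulo orientation relabel
  expect_identical(t_fwd$subject, t_rev$object)
  expect_identical(t_fwd$object, t_rev$subject)
  expect_identical(t_fwd$edge, t_rev$edge)
})

test_that("predicate and category monotonicity hold", {
  sg <- synth_graph(41L, n_nodes = 30L, n_edges = 120L)
  parts <- build_all(sg$graph, sg$model)
  pinned <- names(sg$graph$nodes)[1:3]
  preds <- setdiff(names(sg$model$predicates), sg$model$root_predicate)

  withr::with_seed(13L, {
    for (i in 1:10) {
      p <- sample(preds, 2L)
      t_p1 <- engine_triples(qg(subj = list(ids = pinned), predicates = p[[1L]]),
                             parts, sg$model)
      t_p2 <- engine_triples(qg(subj = list(ids = pinned), predicates = p[[2L]]),
                             parts, sg$model)
      t_union <- engine_triples(qg(subj = list(ids = pinned), predicates = p),
                                parts, sg$model)
      merged <- unique(data.table::rbindlist(list(t_p1, t_p2)))
      data.table::setorder(merged, subject, object, edge)
      expect_identical(t_union, merged[])

      # ancestor predicate answers contain descendant answers
      anc <- sample(sg$model$pred_anc[[p[[1L]]]], 1L)
      t_anc <- engine_triples(qg(subj = list(ids = pinned), predicates = anc),
                              parts, sg$model)
      key <- function(x) paste(x$subject, x$object, x$edge)
      expect_true(all(key(t_p1) %in% key(t_anc)))
    }
    # relaxing the unpinned side's category to an ancestor never loses results
    cats <- setdiff(names(sg$model$categories), sg$model$root_category)
    for (cat in sample(cats, 3L)) {
      anc <- sg$model$cat_anc[[cat]]
      t_cat <- engine_triples(qg(subj = list(ids = pinned),
                                 obj = list(categories = cat)), parts, sg$model)
      t_anc <- engine_triples(qg(subj = list(ids = pinned),
                                 obj = list(categories = sample(anc, 1L))),
                              parts, sg$model)
      key <- function(x) paste(x$subject, x$object, x$edge)
      expect_true(all(key(t_cat) %in% key(t_anc)))
    }
  })
})

test_that("subclass-derived answers carry query_id on their node binding", {
  m <- mini_model()
  g <- make_graph(
    list(make_node("X:parent", "Disease"), make_node("X:child", "Disease"),
         make_node("X:drug", "Drug"), make_node("X:other", "Drug")),
    list(make_edge("s1", "X:child", "subclass_of", "X:parent"),
         make_edge("e1", "X:drug", "treats", "X:child")))
  parts <- build_all(g, m)
  resp <- answer_query(qg(subj = list(ids = "X:parent"), predicates = "treated_by"),
                       parts$index, m, parts$subclass, parts$eqmap)
  expect_length(resp$message$results, 1L)
  nb <- resp$message$results[[1L]]$node_bindings
  expect_identical(nb$n0[[1L]]$id, "X:child")
  expect_identical(nb$n0[[1L]]$query_id, "X:parent")
  expect_null(nb$n1[[1L]]$query_id)
  expect_identical(nb$n1[[1L]]$id, "X:drug")
})
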