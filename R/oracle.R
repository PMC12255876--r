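# Independent brute-force query oracle. This is the referee for the indexed
# engine: it re-derives every reasoning step (hierarchy walks, canonical
# direction, symmetry, equivalence resolution, subclass reachability,
# attribute constraints) with its own naive code, per edge and per query,
# sharing only the input data structures -- never the engine's expansion
# logic or precomputed closures.

#' Brute-force answer to a one-hop query
#'
#' Iterates every edge of the raw graph and tests it against the query by
#' computing, on the fly: the inclusive descendant set of each query
#' predicate (recursive parent-chain walk), the canonical form and symmetry
#' of each candidate predicate (read directly off the model records), the
#' implied ancestor set of the edge's canonical predicate, pinned-id
#' resolution sets (equivalence representative plus naive breadth-first
#' reachability over reversed subclass edges), category membership
#' (ancestor walk over listed categories), and the attribute constraints.
#'
#' @param graph A `kg_graph` (the same input the engine indexed).
#' @param model A `semantic_model` (only its declarative fields are read).
#' @param subclass_edges Data frame/list with `subject`, `predicate`,
#'   `object` of subclass assertions (usually the graph's own
#'   `subclass_of` edges plus any external source).
#' @param eqmap An `equivalence_map` (or `NULL`).
#' @param qgraph Query graph list (same shape as [answer_query()]).
#' @param attribute_map Attribute map as for [answer_query()].
#' @return A sorted `data.table` with columns `subject`, `object`, `edge`:
#'   one row per (subject binding, object binding, edge id) triple, in
#'   query orientation.
#' @export
brute_force_answer <- function(graph, model, subclass_edges = NULL, eqmap = NULL,
                               qgraph, attribute_map = list()) {
  qe <- qgraph$edges[[1L]]
  qn_subj <- qgraph$nodes[[qe$subject]]
  qn_obj <- qgraph$nodes[[qe$object]]

  cat_parents <- lapply(model$categories, `[[`, "parents")
  pred_parents <- lapply(model$predicates, `[[`, "parents")

  anc_walk <- function(parents_map, name) {
    out <- character(0)
    stack <- name
    while (length(stack)) {
      cur <- stack[[1L]]; stack <- stack[-1L]
      if (cur %in% out) next
      out <- c(out, cur)
      stack <- c(stack, parents_map[[cur]])
    }
    out
  }
  desc_walk <- function(parents_map, name) {
    names(parents_map)[vapply(names(parents_map),
                              function(x) name %in% anc_walk(parents_map, x),
                              logical(1))]
  }
  canon_of <- function(p) {
    rec <- model$predicates[[p]]
    if (rec$symmetric || isTRUE(rec$canonical)) list(p = p, flip = FALSE)
    else list(p = rec$inverse, flip = TRUE)
  }

  # pinned-id resolution: representative + naive reachability over reversed
  # subclass edges (cycle-tolerant: a node never resolves to itself twice)
  sc <- if (is.null(subclass_edges)) {
    data.frame(subject = character(0), object = character(0))
  } else {
    as.data.frame(subclass_edges, stringsAsFactors = FALSE)
  }
  resolve_one <- function(q) {
    rep_id <- if (!is.null(eqmap) && length(eqmap$cluster_of)) {
      r <- unname(eqmap$cluster_of[q])
      if (is.na(r)) q else r
    } else q
    reach <- character(0)
    frontier <- rep_id
    while (length(frontier)) {
      kids <- unique(sc$subject[sc$object %in% frontier])
      new <- setdiff(kids, reach)
      reach <- c(reach, new)
      frontier <- new
    }
    unique(c(rep_id, reach))
  }
  side_sets <- function(qn) {
    if (length(qn$ids)) {
      ids <- unique(unlist(lapply(qn$ids, resolve_one)))
      list(mode = "ids", ids = intersect(ids, names(graph$nodes)))
    } else if (length(qn$categories)) {
      list(mode = "cats", cats = norm_name(qn$categories))
    } else {
      list(mode = "any")
    }
  }
  s_side <- side_sets(qn_subj)
  o_side <- side_sets(qn_obj)

  node_cat_closure <- function(id) {
    listed <- intersect(graph$nodes[[id]]$categories, names(model$categories))
    if (length(listed) == 0L) listed <- model$root_category
    unique(unlist(lapply(listed, function(c0) anc_walk(cat_parents, c0))))
  }
  side_match <- function(side, id) {
    switch(side$mode,
           ids = id %in% side$ids,
           cats = length(intersect(side$cats, node_cat_closure(id))) > 0L,
           any = TRUE)
  }

  qpreds <- norm_name(qe$predicates)
  if (length(qpreds) == 0L) qpreds <- model$root_predicate
  want <- unique(unlist(lapply(qpreds, function(p) desc_walk(pred_parents, p))))

  constraints <- qe$attribute_constraints %||% list()
  check_constraints <- function(e) {
    for (con in constraints) {
      prop <- norm_name(con$id)
      for (nm in names(attribute_map)) {
        tid <- attribute_map[[nm]]$attribute_type_id %||% attribute_map[[nm]]
        if (identical(norm_name(as.character(tid)), norm_name(con$id))) prop <- nm
      }
      v <- as.character(unlist(e$properties[[prop]]))
      val <- as.character(unlist(con$value))
      ok <- if (length(v) == 0L) FALSE else switch(con$operator,
        "==" = any(v %in% val),
        "matches" = any(unlist(lapply(val, function(pt) grepl(pt, v)))),
        ">" = any(as.numeric(v) > max(as.numeric(val))),
        "<" = any(as.numeric(v) < min(as.numeric(val))),
        FALSE)
      if (isTRUE(con$not %||% con$negated)) ok <- !ok
      if (!ok) return(FALSE)
    }
    TRUE
  }

  triples <- list()
  for (e in graph$edges) {
    ep <- e$predicate
    if (ep %in% names(model$predicates)) {
      ce <- canon_of(ep)
      es <- if (ce$flip) e$object else e$subject
      eo <- if (ce$flip) e$subject else e$object
      implied <- anc_walk(pred_parents, ce$p)
    } else {
      es <- e$subject; eo <- e$object
      implied <- model$root_predicate
    }
    if (!check_constraints(e)) next
    for (d in want) {
      cd <- canon_of(d)
      if (!cd$p %in% implied) next
      orientations <- if (model$predicates[[cd$p]]$symmetric) {
        list(c(es, eo), c(eo, es))
      } else if (cd$flip) {
        list(c(eo, es))
      } else {
        list(c(es, eo))
      }
      for (orient in orientations) {
        if (side_match(s_side, orient[[1L]]) && side_match(o_side, orient[[2L]])) {
          triples[[length(triples) + 1L]] <-
            c(subject = orient[[1L]], object = orient[[2L]], edge = e$id)
        }
      }
    }
  }
  out <- if (length(triples)) {
    unique(data.table::as.data.table(do.call(rbind, triples)))
  } else {
    data.table::data.table(subject = character(0), object = character(0),
                           edge = character(0))
  }
  data.table::setorder(out, subject, object, edge)
  out[]
}

#' Extract (subject, object, edge) triples from a TRAPI response
#'
#' Companion to [brute_force_answer()]: flattens the engine's response into
#' the same sorted triple table so the two can be compared exactly.
#'
#' @param response A response from [answer_query()].
#' @param subject_key,object_key,edge_key Query-graph keys; defaults taken
#'   from the response's echoed query graph.
#' @return Sorted `data.table` with columns `subject`, `object`, `edge`.
#' @export
response_triples <- function(response, subject_key = NULL, object_key = NULL,
                             edge_key = NULL) {
  qg <- response$message$query_graph
  qe <- qg$edges[[1L]]
  edge_key <- edge_key %||% names(qg$edges)[[1L]]
  subject_key <- subject_key %||% qe$subject
  object_key <- object_key %||% qe$object
  rows <- list()
  for (res in response$message$results) {
    sb <- res$node_bindings[[subject_key]][[1L]]$id
    ob <- res$node_bindings[[object_key]][[1L]]$id
    for (eb in res$analyses[[1L]]$edge_bindings[[edge_key]]) {
      rows[[length(rows) + 1L]] <- c(subject = sb, object = ob, edge = eb$id)
    }
  }
  out <- if (length(rows)) {
    unique(data.table::as.data.table(do.call(rbind, rows)))
  } else {
    data.table::data.table(subject = character(0), object = character(0),
                           edge = character(0))
  }
  data.table::setorder(out, subject, object, edge)
  out[]
}
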