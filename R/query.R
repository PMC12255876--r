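# One-hop TRAPI-shaped query answering over the adjacency index.
#
# A query graph is an R list mirroring the TRAPI message shape:
#   list(nodes = list(n0 = list(ids = ..., categories = ...), n1 = ...),
#        edges = list(e0 = list(subject = "n0", object = "n1",
#                               predicates = ..., attribute_constraints = ...)))

VALID_OPERATORS <- c("==", ">", "<", "matches")

#' Validate a one-hop query graph
#'
#' Checks the structural contract (exactly two query nodes and one query
#' edge whose subject/object name them, at least one node pinned to concrete
#' ids) and that every named category, predicate and constraint operator is
#' known. Fully unpinned queries are rejected: they would enumerate the
#' whole graph rather than look anything up.
#'
#' @param qgraph Query graph list (see module header).
#' @param model A `semantic_model`.
#' @return Character vector of human-readable validation errors; empty iff
#'   the query is answerable.
#' @export
validate_query <- function(qgraph, model) {
  errors <- character(0)
  qnodes <- qgraph$nodes
  qedges <- qgraph$edges
  if (length(qnodes) != 2L || length(qedges) != 1L) {
    return(sprintf("not one-hop: query graph must have exactly 2 nodes and 1 edge (got %d nodes, %d edges)",
                   length(qnodes), length(qedges)))
  }
  qe <- qedges[[1L]]
  for (side in c("subject", "object")) {
    if (is.null(qe[[side]]) || !qe[[side]] %in% names(qnodes)) {
      errors <- c(errors, sprintf("query edge %s '%s' does not name a query node",
                                  side, qe[[side]] %||% "<missing>"))
    }
  }
  if (length(errors) == 0L && identical(qe$subject, qe$object)) {
    errors <- c(errors, "query edge subject and object must be distinct query nodes")
  }
  pinned <- vapply(qnodes, function(qn) length(qn$ids) > 0L, logical(1))
  if (!any(pinned)) {
    errors <- c(errors, "at least one query node must be pinned to concrete ids")
  }
  for (key in names(qnodes)) {
    for (cat in norm_name(qnodes[[key]]$categories)) {
      if (!cat %in% names(model$categories)) {
        errors <- c(errors, sprintf("query node '%s' names unknown category '%s'", key, cat))
      }
    }
  }
  for (p in norm_name(qe$predicates)) {
    if (!p %in% names(model$predicates)) {
      errors <- c(errors, sprintf("query edge names unknown predicate '%s'", p))
    }
  }
  for (con in qe$attribute_constraints %||% list()) {
    if (is.null(con$id) || is.null(con$operator)) {
      errors <- c(errors, "attribute constraint lacks 'id' or 'operator'")
    } else if (!con$operator %in% VALID_OPERATORS) {
      errors <- c(errors, sprintf("unsupported constraint operator '%s'", con$operator))
    }
  }
  errors
}

#' Resolve pinned CURIEs through equivalence and subclass reasoning
#'
#' Each queried CURIE resolves to its equivalence-cluster representative
#' plus all transitive subclass descendants of that representative. Every
#' concrete id maps back to the CURIE the client asked for (its
#' `query_id`); ids absent from the index resolve to nothing. When two
#' queried CURIEs resolve to the same concrete id, the first keeps it.
#'
#' @param ids Non-empty character vector of queried CURIEs.
#' @param eqmap An `equivalence_map` (or `NULL`).
#' @param subclass A `subclass_index` (or `NULL`).
#' @param index A `kg_index`.
#' @return Named character vector: concrete node id -> queried CURIE.
#' @export
resolve_pinned_ids <- function(ids, eqmap = NULL, subclass = NULL, index) {
  out <- character(0)
  for (q in ids) {
    rep_id <- if (is.null(eqmap)) {
      q
    } else if (!is.null(eqmap$cluster_env)) {
      mget(q, envir = eqmap$cluster_env, ifnotfound = q)[[1L]]
    } else if (length(eqmap$cluster_of)) {
      r <- unname(eqmap$cluster_of[q])
      if (is.na(r)) q else r
    } else q
    concrete <- c(rep_id, if (!is.null(subclass)) subclass$descendants_of[[rep_id]])
    concrete <- unique(concrete)
    concrete <- if (!is.null(index$node_env)) {
      concrete[vapply(concrete, exists, logical(1),
                      envir = index$node_env, inherits = FALSE)]
    } else {
      concrete[concrete %in% names(index$node_store)]
    }
    concrete <- setdiff(concrete, names(out))
    if (length(concrete)) out[concrete] <- q
  }
  out
}

#' Evaluate attribute constraints against an edge
#'
#' Constraints are a conjunction. Each constraint id is translated to an
#' edge property through the configured attribute map (matching on
#' `attribute_type_id`), falling back to the raw property name. `==` is
#' membership when either side is multi-valued; `matches` is a regular
#' expression search; `>` and `<` compare numerically and raise a
#' constraint-evaluation error on non-numeric operands. A missing property
#' leaves the constraint unsatisfied (before negation); `not = TRUE`
#' inverts the single constraint's outcome.
#'
#' @param edge A knowledge edge record.
#' @param constraints List of constraints, each
#'   `list(id=, operator=, value=, not=)`.
#' @param attribute_map Named list: edge property ->
#'   `list(attribute_type_id=, value_type=)`.
#' @return Logical flag.
#' @export
apply_attribute_constraints <- function(edge, constraints, attribute_map = list()) {
  if (length(constraints) == 0L) return(TRUE)
  for (con in constraints) {
    prop <- constraint_property(con$id, attribute_map)
    v <- edge$properties[[prop]]
    ok <- if (is.null(v)) FALSE else eval_constraint(v, con)
    if (isTRUE(con$not %||% con$negated)) ok <- !ok
    if (!ok) return(FALSE)
  }
  TRUE
}

constraint_property <- function(id, attribute_map) {
  for (prop in names(attribute_map)) {
    type_id <- attribute_map[[prop]]$attribute_type_id %||% attribute_map[[prop]]
    if (identical(as.character(type_id), id) || identical(norm_name(type_id), norm_name(id))) {
      return(prop)
    }
  }
  norm_name(id)
}

eval_constraint <- function(v, con) {
  v <- unlist(v, use.names = FALSE)
  val <- unlist(con$value, use.names = FALSE)
  switch(con$operator,
    "==" = length(intersect(as.character(v), as.character(val))) > 0L,
    "matches" = any(vapply(as.character(val),
                           function(pat) any(grepl(pat, as.character(v))), logical(1))),
    ">" = ,
    "<" = {
      nv <- suppressWarnings(as.numeric(v))
      nval <- suppressWarnings(as.numeric(val))
      if (anyNA(nv) || anyNA(nval)) {
        stop_onehop("onehop_constraint_error",
                    "constraint '%s' requires numeric operands", con$id)
      }
      if (con$operator == ">") any(nv > max(nval)) else any(nv < min(nval))
    },
    stop_onehop("onehop_constraint_error", "unsupported operator '%s'", con$operator)
  )
}

#' Answer a one-hop query
#'
#' The engine (1) picks the pinned query node (when both are pinned, the one
#' resolving to fewer concrete ids; ties go to the query-edge subject),
#' (2) resolves its ids through equivalence and subclass reasoning,
#' (3) expands query predicates to their descendants and maps each through
#' its canonical form, remembering which flip subject/object, (4) takes the
#' opposite node's categories verbatim (hierarchy expansion already lives in
#' the index), (5) looks up neighbors of every concrete pinned node in the
#' direction implied by the query-edge orientation and the flips (symmetric
#' predicates are direction-free), (6) filters candidate edges by attribute
#' constraints, (7) intersects with the other side's concrete ids when both
#' are pinned, and (8) assembles a TRAPI-shaped response. Results are
#' deduplicated per (subject binding, object binding) pair, sorted by those
#' bindings, and knowledge-graph keys are sorted; answers reached through an
#' equivalent or subclass identifier carry `query_id` on their node binding.
#'
#' @param qgraph Query graph list; must pass [validate_query()].
#' @param index A `kg_index`.
#' @param model A `semantic_model`.
#' @param subclass A `subclass_index` (or `NULL`).
#' @param eqmap An `equivalence_map` (or `NULL`).
#' @param attribute_map Named list mapping edge properties to TRAPI
#'   attribute descriptors.
#' @return TRAPI-shaped response list: `message` (with `query_graph`,
#'   `knowledge_graph`, `results`), `status`, `description`.
#' @export
answer_query <- function(qgraph, index, model, subclass = NULL, eqmap = NULL,
                         attribute_map = list()) {
  qe_key <- names(qgraph$edges)[[1L]]
  qe <- qgraph$edges[[1L]]
  subj_key <- qe$subject
  obj_key <- qe$object
  qnodes <- qgraph$nodes

  resolved <- list()
  for (key in c(subj_key, obj_key)) {
    if (length(qnodes[[key]]$ids)) {
      resolved[[key]] <- resolve_pinned_ids(qnodes[[key]]$ids, eqmap, subclass, index)
    }
  }
  pinned_keys <- names(resolved)
  start_key <- if (length(pinned_keys) == 1L) {
    pinned_keys
  } else if (length(resolved[[obj_key]]) < length(resolved[[subj_key]])) {
    obj_key
  } else {
    subj_key
  }
  other_key <- setdiff(c(subj_key, obj_key), start_key)
  pinned_is_subject <- identical(start_key, subj_key)

  # (3) predicate expansion -> canonical forms grouped by lookup direction
  qpreds <- norm_name(qe$predicates)
  if (length(qpreds) == 0L) qpreds <- model$root_predicate
  desc <- unique(unlist(lapply(qpreds, function(p) model$pred_desc[[p]]),
                        use.names = FALSE))
  canon <- lapply(desc, function(d) canonical_form(model, d))
  cds <- vapply(canon, `[[`, character(1), "predicate")
  flips <- vapply(canon, `[[`, logical(1), "flipped")
  syms <- vapply(cds, function(p) model$predicates[[p]]$symmetric, logical(1))
  dir_of <- ifelse(syms, "out", ifelse(xor(pinned_is_subject, flips), "out", "in"))
  preds_out <- unique(cds[dir_of == "out"])
  preds_in <- unique(cds[dir_of == "in"])

  # (4) opposite node's categories pass through verbatim; on a pinned query
  # node, ids take precedence and categories are ignored
  other_cats <- if (other_key %in% pinned_keys) NULL else qnodes[[other_key]]$categories
  if (!is.null(other_cats)) other_cats <- norm_name(other_cats)

  # (5) gather candidates from every concrete pinned node
  start_ids <- names(resolved[[start_key]])
  cand <- vector("list", 2L * length(start_ids))
  k <- 0L
  for (n in start_ids) {
    if (length(preds_out)) {
      hits <- lookup_neighbors(index, n, other_cats, preds_out, "out")
      if (nrow(hits)) { k <- k + 1L; cand[[k]] <- hits[, pin := n] }
    }
    if (length(preds_in)) {
      hits <- lookup_neighbors(index, n, other_cats, preds_in, "in")
      if (nrow(hits)) { k <- k + 1L; cand[[k]] <- hits[, pin := n] }
    }
  }
  cand <- if (k == 1L) cand[[1L]]
  else if (k) unique(data.table::rbindlist(cand[seq_len(k)]))
  else data.table::data.table(nbr = character(0), eid = character(0),
                              pin = character(0))

  # (6) attribute constraints
  constraints <- qe$attribute_constraints %||% list()
  if (length(constraints) && nrow(cand)) {
    ids <- unique(cand$eid)
    keep_eid <- vapply(store_get(index, "edge", ids), apply_attribute_constraints,
                       logical(1), constraints = constraints,
                       attribute_map = attribute_map)
    cand <- cand[cand$eid %in% ids[keep_eid], ]
  }

  # (7) other side pinned: intersect with its concrete ids
  if (other_key %in% pinned_keys && nrow(cand)) {
    cand <- cand[cand$nbr %in% names(resolved[[other_key]]), ]
  }

  assemble_response(qgraph, qe_key, subj_key, obj_key, pinned_is_subject,
                    cand, resolved, index, attribute_map)
}

assemble_response <- function(qgraph, qe_key, subj_key, obj_key, pinned_is_subject,
                              cand, resolved, index, attribute_map) {
  if (nrow(cand)) {
    sb <- if (pinned_is_subject) cand$pin else cand$nbr
    ob <- if (pinned_is_subject) cand$nbr else cand$pin
    rt <- data.table::data.table(sb = sb, ob = ob, eid = cand$eid)
    data.table::setorder(rt, sb, ob, eid)
    key_vec <- paste(rt$sb, rt$ob, sep = "\x1f")
    # groups aligned positionally with `pairs` (both follow rt's sort order)
    groups <- split(rt$eid, factor(key_vec, levels = unique(key_vec)))
    pairs <- unique(rt[, list(sb, ob)])
  } else {
    groups <- list()
    pairs <- data.table::data.table(sb = character(0), ob = character(0))
  }

  qid_for <- function(key, id) {
    qid <- resolved[[key]][[id]]
    if (!is.null(qid) && !identical(qid, id)) qid else NULL
  }
  results <- lapply(seq_len(nrow(pairs)), function(i) {
    sb <- pairs$sb[[i]]; ob <- pairs$ob[[i]]
    eids <- unique(groups[[i]])
    sb_binding <- list(id = sb)
    qs <- qid_for(subj_key, sb); if (!is.null(qs)) sb_binding$query_id <- qs
    ob_binding <- list(id = ob)
    qo <- qid_for(obj_key, ob); if (!is.null(qo)) ob_binding$query_id <- qo
    list(
      node_bindings = setNames(list(list(sb_binding), list(ob_binding)),
                               c(subj_key, obj_key)),
      analyses = list(list(
        edge_bindings = setNames(list(lapply(eids, function(e) list(id = e))), qe_key)
      ))
    )
  })

  bound_nodes <- sort_c(unique(c(pairs$sb, pairs$ob)))
  bound_edges <- sort_c(unique(if (nrow(cand)) cand$eid else character(0)))
  kg_nodes <- lapply(store_get(index, "node", bound_nodes), serialize_trapi_node,
                     attribute_map = attribute_map)
  kg_edges <- lapply(store_get(index, "edge", bound_edges), serialize_trapi_edge,
                     attribute_map = attribute_map)

  list(
    message = list(
      query_graph = box_query_graph(qgraph),
      knowledge_graph = list(nodes = kg_nodes, edges = kg_edges),
      results = results
    ),
    status = "Success",
    description = sprintf("%d result(s), %d knowledge-graph edge(s)",
                          length(results), length(kg_edges))
  )
}

# Hashed store access: O(length(ids)), not O(store size).
store_get <- function(index, what, ids) {
  env <- index[[paste0(what, "_env")]]
  if (!is.null(env)) mget(ids, envir = env) else
    index[[paste0(what, "_store")]][ids]
}

# Keep TRAPI list-valued fields as JSON arrays even when length 1.
box_query_graph <- function(qgraph) {
  qgraph$nodes <- lapply(qgraph$nodes, function(qn) {
    if (!is.null(qn$ids)) qn$ids <- I(as.character(qn$ids))
    if (!is.null(qn$categories)) qn$categories <- I(as.character(qn$categories))
    qn
  })
  qgraph$edges <- lapply(qgraph$edges, function(qe) {
    if (!is.null(qe$predicates)) qe$predicates <- I(as.character(qe$predicates))
    qe
  })
  qgraph
}

serialize_trapi_node <- function(node, attribute_map = list()) {
  out <- list(name = node$name, categories = I(emit_name(node$categories)))
  attrs <- props_to_attributes(node$properties, attribute_map)
  if (length(node$equivalent_identifiers)) {
    attrs <- c(attrs, list(list(
      attribute_type_id = "biolink:xref",
      value = node$equivalent_identifiers)))
  }
  if (length(attrs)) out$attributes <- attrs
  out
}

serialize_trapi_edge <- function(edge, attribute_map = list()) {
  pks <- as.character(unlist(edge$properties$primary_knowledge_source))
  out <- list(
    subject = edge$subject,
    predicate = emit_name(edge$predicate),
    object = edge$object,
    sources = list(list(
      resource_id = if (length(pks)) pks[[1L]] else "infores:unknown",
      resource_role = "primary_knowledge_source"))
  )
  attrs <- props_to_attributes(
    edge$properties[setdiff(names(edge$properties), "primary_knowledge_source")],
    attribute_map)
  if (length(attrs)) out$attributes <- attrs
  out
}

# Properties become TRAPI attributes through the configured map; unmapped
# properties keep their raw name as attribute_type_id.
props_to_attributes <- function(props, attribute_map) {
  lapply(names(props), function(p) {
    spec <- attribute_map[[p]]
    type_id <- if (is.null(spec)) p else (spec$attribute_type_id %||% spec)
    attr <- list(attribute_type_id = as.character(type_id),
                 value = unlist(props[[p]], use.names = FALSE))
    if (!is.null(spec$value_type)) attr$value_type_id <- spec$value_type
    attr
  })
}
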