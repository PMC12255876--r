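# Schema-level summary of an indexed graph: which (subject category,
# predicate, object category) triples it contains, with counts, plus one
# concrete exemplar edge per meta-edge for external smoke-testing harnesses.

#' Build the meta knowledge graph
#'
#' Iterates the stored canonical (unexpanded) edges; each edge contributes
#' one count under the most specific category of its subject and of its
#' object — by KGX convention the first category listed on the node — and
#' its stored predicate. With `category_policy = "all"` every listed
#' category pair contributes instead (which inflates the count sum above
#' the stored edge count). Per-category `id_prefixes` are collected from
#' observed node CURIE prefixes, ordered by frequency then name; categories
#' with a prefix list in the semantic model use that instead.
#'
#' @param index A `kg_index`.
#' @param model A `semantic_model`.
#' @param category_policy `"most_specific"` (default) or `"all"`.
#' @return An object of class `meta_kg` with fields `meta_nodes` (named
#'   list: category -> `list(id_prefixes=)`) and `meta_edges` (data.table
#'   with columns `subject_category`, `predicate`, `object_category`,
#'   `count`).
#' @export
build_meta_kg <- function(index, model, category_policy = c("most_specific", "all")) {
  category_policy <- match.arg(category_policy)
  node_cats <- lapply(index$node_store, function(n) {
    if (category_policy == "most_specific") n$categories[[1L]] else n$categories
  })

  if (length(index$edge_store)) {
    subj <- vapply(index$edge_store, `[[`, character(1), "subject")
    obj <- vapply(index$edge_store, `[[`, character(1), "object")
    pred <- vapply(index$edge_store, `[[`, character(1), "predicate")
    rows <- if (category_policy == "most_specific") {
      data.table::data.table(
        subject_category = unlist(node_cats[subj], use.names = FALSE),
        predicate = pred,
        object_category = unlist(node_cats[obj], use.names = FALSE),
        eid = names(index$edge_store))
    } else {
      data.table::rbindlist(lapply(seq_along(subj), function(i) {
        data.table::CJ(subject_category = node_cats[[subj[[i]]]],
                       predicate = pred[[i]],
                       object_category = node_cats[[obj[[i]]]],
                       eid = names(index$edge_store)[[i]])
      }))
    }
    meta_edges <- rows[, list(count = .N),
                       by = list(subject_category, predicate, object_category)]
    data.table::setorder(meta_edges, subject_category, predicate, object_category)
  } else {
    rows <- NULL
    meta_edges <- data.table::data.table(
      subject_category = character(0), predicate = character(0),
      object_category = character(0), count = integer(0))
  }

  used_cats <- sort_c(unique(c(meta_edges$subject_category, meta_edges$object_category)))
  meta_nodes <- setNames(lapply(used_cats, function(cat) {
    declared <- model$category_prefixes[[cat]]
    if (!is.null(declared)) return(list(id_prefixes = declared))
    members <- names(node_cats)[vapply(node_cats, function(cs) cat %in% cs, logical(1))]
    prefixes <- sub(":.*$", "", members)
    tab <- sort(table(prefixes), decreasing = TRUE)
    ord <- names(tab)[order(-as.integer(tab), names(tab), method = "radix")]
    list(id_prefixes = ord)
  }), used_cats)

  structure(list(meta_nodes = meta_nodes, meta_edges = meta_edges,
                 category_policy = category_policy, edge_rows = rows),
            class = "meta_kg")
}

#' Select one exemplar test triple per meta-edge
#'
#' For each meta-edge, deterministically selects one stored edge matching
#' it: edge ids are ranked by a seed-keyed hash and the smallest wins, so a
#' fixed seed always yields the same triples while different seeds sample
#' different exemplars.
#'
#' @param index A `kg_index`.
#' @param metakg A `meta_kg` built from the same index.
#' @param seed Integer selection key.
#' @return Object of class `test_triples`: a data.table with columns
#'   `subject_category`, `predicate`, `object_category`, `subject_id`,
#'   `object_id`.
#' @export
build_test_triples <- function(index, metakg, seed = 0L) {
  me <- metakg$meta_edges
  if (nrow(me) == 0L) {
    return(structure(data.table::data.table(
      subject_category = character(0), predicate = character(0),
      object_category = character(0), subject_id = character(0),
      object_id = character(0)), class = c("test_triples", "data.table", "data.frame")))
  }
  rows <- data.table::copy(metakg$edge_rows)
  rows[, rank := vapply(paste0(seed, "\x1f", eid),
                        function(s) digest::digest(s, algo = "sha1", serialize = FALSE),
                        character(1))]
  data.table::setorder(rows, rank, eid)
  pick <- rows[!duplicated(paste(subject_category, predicate, object_category, sep = "\x1f"))]
  triples <- pick[, list(
    subject_category, predicate, object_category,
    subject_id = vapply(eid, function(e) index$edge_store[[e]]$subject, character(1)),
    object_id = vapply(eid, function(e) index$edge_store[[e]]$object, character(1)))]
  data.table::setorder(triples, subject_category, predicate, object_category)
  structure(triples, class = c("test_triples", "data.table", "data.frame"))
}

# TRAPI JSON shapes for the two deployment endpoints.
meta_kg_to_trapi <- function(metakg) {
  nodes <- setNames(lapply(names(metakg$meta_nodes), function(cat) {
    list(id_prefixes = metakg$meta_nodes[[cat]]$id_prefixes)
  }), emit_name(names(metakg$meta_nodes)))
  edges <- lapply(seq_len(nrow(metakg$meta_edges)), function(i) {
    r <- metakg$meta_edges[i]
    list(subject = emit_name(r$subject_category),
         predicate = emit_name(r$predicate),
         object = emit_name(r$object_category),
         count = r$count)
  })
  list(nodes = nodes, edges = edges)
}

test_triples_to_json <- function(triples) {
  lapply(seq_len(nrow(triples)), function(i) {
    r <- triples[i]
    list(subject_category = emit_name(r$subject_category),
         predicate = emit_name(r$predicate),
         object_category = emit_name(r$object_category),
         subject_id = r$subject_id,
         object_id = r$object_id)
  })
}

#' @export
print.meta_kg <- function(x, ...) {
  cat(sprintf("<meta_kg> %d meta-nodes, %d meta-edges, %s-category counting\n",
              length(x$meta_nodes), nrow(x$meta_edges), x$category_policy))
  invisible(x)
}
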