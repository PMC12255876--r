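# The core in-memory structure: a nested adjacency map
# node -> neighbor-category -> predicate -> direction -> {(neighbor, edge)},
# realized as a keyed data.table so lookups are a binary-search join.
# All hierarchy / symmetry / canonical-direction reasoning is baked in at
# build time: an edge is registered under every ancestor of its canonical
# predicate and every ancestor of each neighbor category, so query terms are
# looked up verbatim with no descendant walk at query time.

SNAPSHOT_FORMAT_VERSION <- 1L

#' Build the adjacency index for a knowledge graph
#'
#' Every edge is first put into canonical form: the non-canonical member of
#' an inverse predicate pair is replaced by its inverse with subject and
#' object swapped (the flip is recorded on the stored edge). The canonical
#' edge is then registered under all inclusive ancestors of its canonical
#' predicate; under each such key predicate, a symmetric predicate registers
#' the pair from both endpoints in direction `out`, a directional one from
#' the subject (`out`) and the object (`in`). Neighbor-category keys cover
#' all categories listed on the neighbor plus their ancestors.
#'
#' Edges whose predicate is unknown to the semantic model are indexed under
#' the root predicate only, with a counted warning.
#'
#' @param graph A `kg_graph`.
#' @param model A `semantic_model`.
#' @param options Optional list of build options (recorded in `build_meta`).
#' @param log Optional internal log environment.
#' @return An object of class `kg_index`.
#' @export
build_index <- function(graph, model, options = list(), log = NULL) {
  node_ids <- names(graph$nodes)
  edge_ids <- names(graph$edges)

  # canonical predicate / flip lookup tables over the model
  pred_names <- names(model$predicates)
  canon_pred <- vapply(pred_names, function(p) canonical_form(model, p)$predicate,
                       character(1))
  canon_flip <- vapply(pred_names, function(p) canonical_form(model, p)$flipped,
                       logical(1))
  sym_flag <- vapply(pred_names, function(p) model$predicates[[p]]$symmetric, logical(1))

  subj <- vapply(graph$edges, `[[`, character(1), "subject")
  obj  <- vapply(graph$edges, `[[`, character(1), "object")
  pred <- vapply(graph$edges, `[[`, character(1), "predicate")

  unknown <- !(pred %in% pred_names)
  n_unknown <- sum(unknown)
  if (n_unknown > 0L) {
    log_msg(log, "WARN", "%d edges with predicates unknown to the model indexed under root '%s'",
            n_unknown, model$root_predicate)
  }
  cp <- ifelse(unknown, pred, canon_pred[pred])
  flip <- ifelse(unknown, FALSE, canon_flip[pred])
  s2 <- ifelse(flip, obj, subj)
  o2 <- ifelse(flip, subj, obj)

  edge_store <- vector("list", length(edge_ids))
  names(edge_store) <- edge_ids
  for (i in seq_along(edge_ids)) {
    e <- graph$edges[[i]]
    e$subject <- s2[[i]]; e$object <- o2[[i]]; e$predicate <- cp[[i]]
    e$flipped <- unname(flip[[i]])
    if (unknown[[i]]) e$properties$original_predicate <- pred[[i]]
    edge_store[[i]] <- e
  }

  # ancestor-expanded categories per node
  cats_of <- lapply(graph$nodes, function(n) {
    listed <- intersect(n$categories, names(model$categories))
    unique(c(unlist(model$cat_anc[listed], use.names = FALSE), model$root_category))
  })
  node_cats <- data.table::data.table(
    node = rep(node_ids, lengths(cats_of)),
    ncat = as.character(unlist(cats_of, use.names = FALSE)))

  if (length(edge_ids)) {
    # key predicates: inclusive ancestors of the canonical predicate
    # (root only, for model-unknown predicates)
    anc_of <- model$pred_anc[cp]
    anc_of[unknown] <- list(model$root_predicate)
    et <- data.table::data.table(
      eid = rep(edge_ids, lengths(anc_of)),
      s = rep(s2, lengths(anc_of)),
      o = rep(o2, lengths(anc_of)),
      ap = unlist(anc_of, use.names = FALSE))
    et[, sym := sym_flag[ap]]
    regs <- data.table::rbindlist(list(
      et[, list(node = s, nbr = o, pred = ap, dir = "out", eid = eid)],
      et[, list(node = o, nbr = s, pred = ap,
                dir = data.table::fifelse(sym, "out", "in"), eid = eid)]))
    adj <- merge(regs, node_cats, by.x = "nbr", by.y = "node",
                 allow.cartesian = TRUE)
    adj <- unique(adj[, list(node, ncat, pred, dir, nbr, eid)])
  } else {
    adj <- data.table::data.table(node = character(0), ncat = character(0),
                                  pred = character(0), dir = character(0),
                                  nbr = character(0), eid = character(0))
  }
  data.table::setorder(adj, node, ncat, pred, dir, nbr, eid)
  data.table::setkey(adj, node, ncat, pred, dir)

  nodes_by_category <- unique(node_cats[, list(category = ncat, node = node)])
  data.table::setorder(nodes_by_category, category, node)
  data.table::setkey(nodes_by_category, category)

  structure(list(
    adj = adj,
    nodes_by_category = nodes_by_category,
    edge_store = edge_store,
    node_store = graph$nodes,
    # hashed views for O(1) per-id access on large stores
    node_env = list2env(as.list(graph$nodes), hash = TRUE, parent = emptyenv()),
    edge_env = list2env(as.list(edge_store), hash = TRUE, parent = emptyenv()),
    root_category = model$root_category,
    root_predicate = model$root_predicate,
    build_meta = list(
      model_checksum = model$checksum,
      provenance = graph$provenance[c("nodes_source", "edges_source", "dialect")],
      options = options,
      n_nodes = length(node_ids),
      n_edges = length(edge_ids),
      warnings = list(unknown_predicate_edges = n_unknown)
    )
  ), class = "kg_index")
}

#' Constant-time neighbor lookup
#'
#' Unions the stored pair sets over the requested neighbor-category,
#' predicate and direction keys. Because hierarchy expansion happened at
#' build time, callers pass query terms verbatim; `NULL` categories or
#' predicates mean "all" (served by the root keys, which dominate every
#' stored pair), while an explicit empty set returns nothing. An unknown
#' node yields an empty result, not an error.
#'
#' @param index A `kg_index`.
#' @param node Node CURIE.
#' @param neighbor_categories Character vector of category names, or `NULL`
#'   for all.
#' @param predicates Character vector of predicate names, or `NULL` for all.
#' @param direction `"out"`, `"in"`, or `"any"`.
#' @return A `data.table` with columns `nbr` (neighbor CURIE) and `eid`
#'   (edge id), one row per distinct pair.
#' @export
lookup_neighbors <- function(index, node, neighbor_categories = NULL,
                             predicates = NULL, direction = c("any", "out", "in")) {
  direction <- match.arg(direction)
  empty <- data.table::data.table(nbr = character(0), eid = character(0))
  if (!is.null(neighbor_categories) && length(neighbor_categories) == 0L) return(empty)
  if (!is.null(predicates) && length(predicates) == 0L) return(empty)
  cats <- if (is.null(neighbor_categories)) index$root_category
          else unique(norm_name(neighbor_categories))
  preds <- if (is.null(predicates)) index$root_predicate
           else unique(norm_name(predicates))
  dirs <- if (direction == "any") c("out", "in") else direction
  # built outside the join so argument names cannot collide with columns
  probe <- data.table::CJ(node = node, ncat = cats, pred = preds, dir = dirs)
  hits <- index$adj[probe, nomatch = 0L][, list(nbr, eid)]
  # adj rows are globally unique, so a single-key probe cannot duplicate pairs
  if (nrow(probe) == 1L) hits else unique(hits)
}

#' Transitive subclass closure over a graph
#'
#' Collects subclass edges (`child subclass_of parent`) from the graph,
#' optionally unioned with an external edge list, and computes for every
#' node the set of its transitive subclass descendants by breadth-first
#' reachability over reversed subclass edges, up to `max_depth` hops.
#' Cycles are tolerated: members of a cycle reach each other but are never
#' listed as their own descendants.
#'
#' @param graph A `kg_graph`.
#' @param external_edges Optional data.frame/list with `subject`,
#'   `predicate`, `object` columns to union in (e.g. from an ontology file).
#' @param subclass_predicates Predicate names treated as subclass assertions.
#' @param max_depth Positive integer or `Inf` (full transitive chaining).
#' @param log Optional internal log environment.
#' @return An object of class `subclass_index` with field `descendants_of`
#'   (named list: node -> character vector of descendants, self excluded).
#' @export
build_subclass_closure <- function(graph, external_edges = NULL,
                                   subclass_predicates = "subclass_of",
                                   max_depth = Inf, log = NULL) {
  if (length(subclass_predicates) == 0L) {
    stop_onehop("onehop_config_error", "subclass_predicates must be non-empty")
  }
  subclass_predicates <- norm_name(subclass_predicates)
  child <- character(0); parent <- character(0)
  for (e in graph$edges) {
    if (e$predicate %in% subclass_predicates) {
      child <- c(child, e$subject); parent <- c(parent, e$object)
    }
  }
  if (!is.null(external_edges)) {
    ext <- as.data.frame(external_edges, stringsAsFactors = FALSE)
    keep <- norm_name(ext$predicate) %in% subclass_predicates
    child <- c(child, ext$subject[keep]); parent <- c(parent, ext$object[keep])
  }

  descendants_of <- list()
  n_cycles <- 0L
  if (length(child)) {
    kids <- split(child, parent)   # parent -> immediate children
    all_nodes <- sort_c(unique(c(child, parent)))
    for (x in all_nodes) {
      seen <- character(0)
      frontier <- unique(kids[[x]])
      depth <- 1L
      while (length(frontier) && depth <= max_depth) {
        new <- setdiff(frontier, seen)
        if (!length(new)) break
        seen <- c(seen, new)
        frontier <- unique(unlist(kids[new], use.names = FALSE))
        depth <- depth + 1L
      }
      if (x %in% seen) {
        n_cycles <- n_cycles + 1L
        seen <- setdiff(seen, x)
      }
      if (length(seen)) descendants_of[[x]] <- sort_c(seen)
    }
    if (n_cycles > 0L) {
      log_msg(log, "WARN", "subclass closure: %d nodes participate in cycles", n_cycles)
    }
  }
  structure(list(
    descendants_of = descendants_of,
    source = list(subclass_predicates = subclass_predicates,
                  n_graph_edges = length(child),
                  max_depth = max_depth, n_cycle_nodes = n_cycles)
  ), class = "subclass_index")
}

#' Persist the engine's indexes to a snapshot directory
#'
#' Writes a versioned, deterministic on-disk snapshot: a JSON manifest
#' (format version, semantic-model checksum, build metadata), the node and
#' edge stores as JSON Lines, the adjacency and category tables as TSV, and
#' the subclass/equivalence structures as JSON. [load_index()] on the
#' snapshot restores structures that answer every query identically.
#'
#' @param index A `kg_index`.
#' @param subclass A `subclass_index` (or `NULL`).
#' @param eqmap An `equivalence_map` (or `NULL`).
#' @param target Snapshot directory (created if needed).
#' @export
save_index <- function(index, subclass = NULL, eqmap = NULL, target) {
  dir.create(target, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(target)) {
    stop_onehop("onehop_io_error", "cannot create snapshot directory %s", target)
  }
  manifest <- list(
    format_version = SNAPSHOT_FORMAT_VERSION,
    root_category = index$root_category,
    root_predicate = index$root_predicate,
    build_meta = index$build_meta,
    subclass_source = if (!is.null(subclass)) subclass$source else NULL
  )
  jsonlite::write_json(manifest, file.path(target, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  write_jsonl(index$node_store[sort_c(names(index$node_store))],
              file.path(target, "nodes.jsonl"))
  write_jsonl(index$edge_store[sort_c(names(index$edge_store))],
              file.path(target, "edges.jsonl"))
  data.table::fwrite(index$adj, file.path(target, "adjacency.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(index$nodes_by_category, file.path(target, "nodes_by_category.tsv"),
                     sep = "\t", quote = FALSE)
  jsonlite::write_json(
    if (is.null(subclass)) list() else subclass$descendants_of,
    file.path(target, "subclass.json"), digits = NA)
  jsonlite::write_json(
    if (is.null(eqmap)) list() else as.list(eqmap$cluster_of),
    file.path(target, "eqmap.json"), auto_unbox = TRUE, digits = NA)
  invisible(target)
}

#' Load a snapshot written by [save_index()]
#'
#' Distinguishes three failure modes: a missing snapshot, a corrupt one
#' (unreadable manifest or missing component files), and a format-version
#' mismatch; each raises a distinct error class.
#'
#' @param source Snapshot directory.
#' @return List with elements `index`, `subclass`, `eqmap`.
#' @export
load_index <- function(source) {
  man_path <- file.path(source, "manifest.json")
  if (!dir.exists(source) || !file.exists(man_path)) {
    stop_onehop("onehop_snapshot_missing", "no snapshot at %s", source)
  }
  manifest <- tryCatch(jsonlite::fromJSON(man_path, simplifyVector = FALSE),
                       error = function(e) NULL)
  if (is.null(manifest) || is.null(manifest$format_version)) {
    stop_onehop("onehop_snapshot_corrupt", "snapshot manifest at %s is unreadable", source)
  }
  if (!identical(as.integer(manifest$format_version), SNAPSHOT_FORMAT_VERSION)) {
    stop_onehop("onehop_snapshot_version",
                "snapshot format version %s != supported %d",
                manifest$format_version, SNAPSHOT_FORMAT_VERSION)
  }
  parts <- c("nodes.jsonl", "edges.jsonl", "adjacency.tsv", "nodes_by_category.tsv",
             "subclass.json", "eqmap.json")
  missing <- parts[!file.exists(file.path(source, parts))]
  if (length(missing)) {
    stop_onehop("onehop_snapshot_corrupt", "snapshot at %s lacks %s",
                source, paste(missing, collapse = ", "))
  }

  read_store <- function(path, as_node) {
    lines <- readLines(path, warn = FALSE)
    recs <- lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
    out <- lapply(recs, function(r) {
      r$properties <- as.list(r$properties)
      if (as_node) {
        r$categories <- as.character(unlist(r$categories))
        r$equivalent_identifiers <- as.character(unlist(r$equivalent_identifiers))
      }
      r
    })
    setNames(out, vapply(out, `[[`, character(1), "id"))
  }
  node_store <- read_store(file.path(source, "nodes.jsonl"), as_node = TRUE)
  edge_store <- read_store(file.path(source, "edges.jsonl"), as_node = FALSE)

  adj <- data.table::fread(file.path(source, "adjacency.tsv"), sep = "\t",
                           colClasses = "character", showProgress = FALSE)
  data.table::setkey(adj, node, ncat, pred, dir)
  nbc <- data.table::fread(file.path(source, "nodes_by_category.tsv"), sep = "\t",
                           colClasses = "character", showProgress = FALSE)
  data.table::setkey(nbc, category)

  desc <- jsonlite::fromJSON(file.path(source, "subclass.json"), simplifyVector = TRUE)
  desc <- lapply(as.list(desc), function(v) as.character(unlist(v)))
  cluster_raw <- jsonlite::fromJSON(file.path(source, "eqmap.json"), simplifyVector = TRUE)
  cluster_of <- unlist(as.list(cluster_raw))
  if (is.null(cluster_of)) cluster_of <- character(0)

  index <- structure(list(
    adj = adj, nodes_by_category = nbc,
    edge_store = edge_store, node_store = node_store,
    node_env = list2env(as.list(node_store), hash = TRUE, parent = emptyenv()),
    edge_env = list2env(as.list(edge_store), hash = TRUE, parent = emptyenv()),
    root_category = manifest$root_category,
    root_predicate = manifest$root_predicate,
    build_meta = manifest$build_meta
  ), class = "kg_index")
  subclass <- structure(list(descendants_of = desc,
                             source = manifest$subclass_source %||% list()),
                        class = "subclass_index")
  members_of <- if (length(cluster_of)) {
    lapply(split(names(cluster_of), cluster_of), sort_c)
  } else list()
  eqmap <- structure(list(cluster_of = cluster_of, members_of = members_of,
                          cluster_env = list2env(as.list(cluster_of), hash = TRUE,
                                                 parent = emptyenv())),
                     class = "equivalence_map")
  list(index = index, subclass = subclass, eqmap = eqmap)
}

#' @export
print.kg_index <- function(x, ...) {
  cat(sprintf("<kg_index> %d nodes, %d canonical edges, %d adjacency entries\n",
              x$build_meta$n_nodes %||% length(x$node_store),
              length(x$edge_store), nrow(x$adj)))
  invisible(x)
}

#' @export
print.subclass_index <- function(x, ...) {
  cat(sprintf("<subclass_index> %d nodes with descendants\n", length(x$descendants_of)))
  invisible(x)
}
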