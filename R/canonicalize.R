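# Entity resolution: cluster equivalent CURIEs and merge each cluster into a
# single representative node, so that queries pinned to any member answer
# against one canonical concept.

#' File-backed identifier resolver
#'
#' A resolver maps a batch of CURIEs to their equivalence cluster, honouring
#' the contract of an external node-normalization service: every queried
#' CURIE gets an entry (a singleton if nothing is known). This constructor
#' builds an offline resolver from a JSON file mapping
#' `CURIE -> {members: [...], preferred: CURIE}`, which keeps the engine
#' buildable without network access.
#'
#' @param path JSON stub file.
#' @return A function `f(curies)` returning a named list of
#'   `list(members=..., preferred=...)` records, one per queried CURIE.
#' @export
file_resolver <- function(path) {
  if (!file.exists(path)) {
    stop_onehop("onehop_io_error", "resolver stub file not found: %s", path)
  }
  table <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  function(curies) {
    setNames(lapply(curies, function(id) {
      rec <- table[[id]]
      if (is.null(rec)) {
        list(members = id, preferred = id)
      } else {
        list(members = unique(c(id, as.character(unlist(rec$members)))),
             preferred = as.character(rec$preferred %||% id))
      }
    }), curies)
  }
}

#' Build an equivalence map over a graph's nodes
#'
#' Runs union--find over each node's own id together with its equivalent
#' identifiers. When a node carries no equivalence property and a resolver
#' is supplied, the resolver's cluster for that node is used instead; with
#' neither, the node forms a singleton cluster. A failing resolver degrades
#' to singletons with a warning rather than aborting the build.
#'
#' Nodes are processed in sorted-id order and path compression is applied,
#' so cluster membership and representatives are reproducible.
#'
#' @param graph A `kg_graph`.
#' @param resolver Optional resolver function (see [file_resolver()]).
#' @param prefix_priority Ordered CURIE prefixes used by
#'   [choose_preferred_id()] to pick each cluster's representative.
#' @param log Optional internal log environment.
#' @return An object of class `equivalence_map` with fields `cluster_of`
#'   (named character: member -> representative) and `members_of`
#'   (named list: representative -> members).
#' @export
build_equivalence_map <- function(graph, resolver = NULL,
                                  prefix_priority = character(0), log = NULL) {
  ids <- sort_c(names(graph$nodes))
  parent <- new.env(parent = emptyenv())
  find <- function(x) {
    root <- x
    while (!identical(parent[[root]], root)) root <- parent[[root]]
    while (!identical(parent[[x]], root)) { nxt <- parent[[x]]; parent[[x]] <- root; x <- nxt }
    root
  }
  ensure <- function(x) if (is.null(parent[[x]])) parent[[x]] <- x
  union_ <- function(a, b) {
    ensure(a); ensure(b)
    ra <- find(a); rb <- find(b)
    if (!identical(ra, rb)) {
      # deterministic: smaller string becomes the root
      if (ra < rb) parent[[rb]] <- ra else parent[[ra]] <- rb
    }
  }

  need_resolver <- character(0)
  # positional access: nodes are already stored sorted by id
  eq_lists <- lapply(graph$nodes, `[[`, "equivalent_identifiers")[ids]
  for (i in seq_along(ids)) {
    id <- ids[[i]]
    ensure(id)
    eq <- eq_lists[[i]]
    if (length(eq)) {
      for (other in eq) union_(id, other)
    } else if (!is.null(resolver)) {
      need_resolver <- c(need_resolver, id)
    }
  }
  if (length(need_resolver)) {
    res <- tryCatch(resolver(need_resolver), error = function(e) {
      log_msg(log, "WARN", "resolver failed (%s); falling back to singleton clusters",
              conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      for (id in need_resolver) {
        for (other in res[[id]]$members %||% id) union_(id, other)
      }
    }
  }

  members <- ls(parent, sorted = TRUE)
  root_of <- vapply(members, find, character(1))
  clusters <- split(members, root_of)

  reps <- vapply(clusters, function(cl) {
    if (length(cl) == 1L) cl else choose_preferred_id(cl, prefix_priority)
  }, character(1))
  members_of <- setNames(lapply(clusters, sort_c), reps)
  cluster_of <- setNames(rep(reps, lengths(clusters)),
                         unlist(clusters, use.names = FALSE))
  cluster_of <- cluster_of[sort_c(names(cluster_of))]
  structure(list(cluster_of = cluster_of,
                 members_of = members_of[sort_c(names(members_of))],
                 cluster_env = list2env(as.list(cluster_of), hash = TRUE,
                                        parent = emptyenv())),
            class = "equivalence_map")
}

#' Pick a cluster's representative CURIE
#'
#' The member whose prefix ranks earliest in `prefix_priority` wins; ties and
#' members with unlisted prefixes fall back to lexicographic order on the
#' full CURIE string (so `"X:10" < "X:2"`: the ordering is textual, not
#' numeric).
#'
#' @param members Non-empty character vector of CURIEs.
#' @param prefix_priority Ordered character vector of preferred prefixes.
#' @return A single CURIE.
#' @export
choose_preferred_id <- function(members, prefix_priority = character(0)) {
  if (length(members) == 0L) {
    stop_onehop("onehop_format_error", "cannot pick a representative of an empty cluster")
  }
  members <- sort_c(unique(members))
  prefixes <- sub(":.*$", "", members)
  rank <- match(prefixes, prefix_priority)
  rank[is.na(rank)] <- length(prefix_priority) + 1L
  members[order(rank, members, method = "radix")][1L]
}

#' Merge equivalent nodes into canonical representatives
#'
#' Produces a graph with one node per equivalence cluster, keyed by the
#' cluster representative. Merged nodes take the union of member categories
#' (first-seen order, representative first), the representative's name, and
#' all member ids as `equivalent_identifiers`; conflicting scalar properties
#' keep the representative's value and stash the others under a
#' `_merged_values` property. Edges are re-pointed to representatives;
#' self-loops created by merging are kept; edges made identical by
#' re-pointing (same subject, object, predicate and
#' `primary_knowledge_source`) are merged with list-valued properties
#' concatenated and deduplicated. A second pass is the identity.
#'
#' @param graph A `kg_graph`.
#' @param eqmap An `equivalence_map` covering all node ids of `graph`.
#' @return A new `kg_graph`.
#' @export
canonicalize_graph <- function(graph, eqmap) {
  rep_of <- function(id) {
    r <- eqmap$cluster_of[[id]]
    if (is.null(r) || is.na(r)) id else r
  }

  node_groups <- split(names(graph$nodes),
                       vapply(names(graph$nodes), rep_of, character(1)))
  nodes <- list()
  for (rep_id in sort_c(names(node_groups))) {
    member_ids <- node_groups[[rep_id]]
    # representative's own record first (if present in the graph), then the
    # remaining members in sorted order
    ord <- c(intersect(rep_id, member_ids), sort_c(setdiff(member_ids, rep_id)))
    recs <- graph$nodes[ord]
    base <- recs[[1L]]
    merged <- list(
      id = rep_id,
      name = base$name,
      categories = unique(unlist(lapply(recs, `[[`, "categories"))),
      equivalent_identifiers = sort_c(setdiff(unique(c(
        unlist(eqmap$members_of[[rep_id]] %||% member_ids),
        unlist(lapply(recs, `[[`, "equivalent_identifiers")))), rep_id)),
      properties = base$properties
    )
    if (length(recs) > 1L) {
      extra <- list()
      for (rec in recs[-1L]) {
        for (p in names(rec$properties)) {
          cur <- merged$properties[[p]]
          v <- rec$properties[[p]]
          if (is.null(cur)) {
            merged$properties[[p]] <- v
          } else if (length(cur) > 1L || length(v) > 1L) {
            merged$properties[[p]] <- unique(c(unlist(cur), unlist(v)))
          } else if (!identical(as.character(cur), as.character(v))) {
            extra[[p]] <- unique(c(unlist(extra[[p]]), as.character(v)))
          }
        }
      }
      if (length(extra)) merged$properties[["_merged_values"]] <- extra
    }
    nodes[[rep_id]] <- merged
  }

  edges <- list()
  dedup_key <- new.env(parent = emptyenv())
  for (eid in names(graph$edges)) {
    e <- graph$edges[[eid]]
    e$subject <- rep_of(e$subject)
    e$object <- rep_of(e$object)
    key <- paste(e$subject, e$object, e$predicate,
                 paste(as.character(unlist(e$properties$primary_knowledge_source)),
                       collapse = ","), sep = "\x1f")
    prev <- dedup_key[[key]]
    if (is.null(prev)) {
      dedup_key[[key]] <- e$id
      edges[[e$id]] <- e
    } else {
      kept <- edges[[prev]]
      for (p in names(e$properties)) {
        cur <- kept$properties[[p]]
        kept$properties[[p]] <- if (is.null(cur)) e$properties[[p]] else
          unique(c(unlist(cur), unlist(e$properties[[p]])))
      }
      edges[[prev]] <- kept
    }
  }

  structure(list(
    nodes = nodes[sort_c(names(nodes))],
    edges = edges[sort_c(names(edges))],
    provenance = c(graph$provenance[setdiff(names(graph$provenance), "canonicalized")],
                   list(canonicalized = TRUE))
  ), class = "kg_graph")
}

#' @export
print.equivalence_map <- function(x, ...) {
  sizes <- lengths(x$members_of)
  cat(sprintf("<equivalence_map> %d CURIEs in %d clusters (largest: %d)\n",
              length(x$cluster_of), length(x$members_of),
              if (length(sizes)) max(sizes) else 0L))
  invisible(x)
}
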