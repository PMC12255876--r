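#' Read a knowledge graph from KGX flat files
#'
#' Materializes a KGX-formatted graph (separate nodes and edges files, in
#' either the TSV or the JSON Lines dialect) as a validated in-memory
#' `kg_graph`. Sources may be local paths or http(s) URLs; URLs are fetched
#' once into a cache directory keyed by a hash of the URL.
#'
#' Load policy, applied in this order:
#' \itemize{
#'   \item nodes with a duplicate `id`: last occurrence wins (warning counted);
#'   \item nodes with an empty `category`: assigned `root_category`;
#'   \item edges with a duplicate `id`: deterministically re-suffixed
#'     (`#2`, `#3`, ...);
#'   \item edges without an `id`: assigned a stable hash of
#'     subject/predicate/object/primary_knowledge_source;
#'   \item dangling edges (subject or object absent from the nodes file):
#'     dropped, with the count recorded in `provenance$warnings`.
#' }
#' Nodes and edges are stored sorted by id, so loading the same files twice
#' yields identical objects.
#'
#' @param nodes_source,edges_source Path or URL of the KGX nodes / edges file.
#' @param dialect `"tsv"`, `"jsonlines"`, or `"auto"` (sniff by file
#'   extension, then by whether the first byte is `{`).
#' @param list_delimiter Separator for multi-valued fields in the TSV dialect.
#' @param equivalent_identifiers_property Name of the node property carrying
#'   equivalent CURIEs.
#' @param root_category Category assigned to nodes that list none.
#' @param cache_dir Directory for fetched URL sources (default `tempdir()`).
#' @param log Optional internal log environment.
#' @return An object of class `kg_graph` with fields `nodes`, `edges`,
#'   `provenance`.
#' @export
read_graph <- function(nodes_source, edges_source,
                       dialect = c("auto", "tsv", "jsonlines"),
                       list_delimiter = "|",
                       equivalent_identifiers_property = "equivalent_identifiers",
                       root_category = "NamedThing",
                       cache_dir = NULL, log = NULL) {
  dialect <- match.arg(dialect)
  nodes_path <- fetch_source(nodes_source, cache_dir)
  edges_path <- fetch_source(edges_source, cache_dir)
  ndialect <- if (dialect == "auto") sniff_dialect(nodes_path) else dialect
  edialect <- if (dialect == "auto") sniff_dialect(edges_path) else dialect

  nrecs <- read_kgx_records(nodes_path, ndialect, list_delimiter)
  erecs <- read_kgx_records(edges_path, edialect, list_delimiter)
  warnings <- list(duplicate_nodes = 0L, duplicate_edge_ids = 0L, dangling_edges = 0L)

  nodes <- list()
  for (i in seq_along(nrecs)) {
    rec <- nrecs[[i]]
    if (is.null(rec$id) || !nzchar(rec$id)) {
      stop_onehop("onehop_format_error", "nodes file %s: record %d lacks 'id'",
                  nodes_source, i)
    }
    if (!is_curie(rec$id)) {
      stop_onehop("onehop_format_error",
                  "nodes file %s: record %d id '%s' is not a CURIE", nodes_source, i, rec$id)
    }
    node <- as_knowledge_node(rec, equivalent_identifiers_property, root_category)
    if (!is.null(nodes[[node$id]])) {
      warnings$duplicate_nodes <- warnings$duplicate_nodes + 1L
      log_msg(log, "WARN", "duplicate node id '%s': keeping last occurrence", node$id)
    }
    nodes[[node$id]] <- node
  }

  edges <- list()
  for (i in seq_along(erecs)) {
    rec <- erecs[[i]]
    for (f in c("subject", "predicate", "object")) {
      if (is.null(rec[[f]]) || !nzchar(rec[[f]])) {
        stop_onehop("onehop_format_error", "edges file %s: record %d lacks '%s'",
                    edges_source, i, f)
      }
    }
    if (is.null(nodes[[rec$subject]]) || is.null(nodes[[rec$object]])) {
      warnings$dangling_edges <- warnings$dangling_edges + 1L
      log_msg(log, "WARN", "dropping dangling edge %s -%s-> %s",
              rec$subject, rec$predicate, rec$object)
      next
    }
    edge <- as_knowledge_edge(rec)
    if (!nzchar(edge$id)) {
      edge$id <- synth_edge_id(edge$subject, edge$predicate, edge$object,
                               edge$properties$primary_knowledge_source %||% "")
    }
    if (!is.null(edges[[edge$id]])) {
      warnings$duplicate_edge_ids <- warnings$duplicate_edge_ids + 1L
      k <- 2L
      while (!is.null(edges[[paste0(edge$id, "#", k)]])) k <- k + 1L
      edge$id <- paste0(edge$id, "#", k)
    }
    edges[[edge$id]] <- edge
  }

  nodes <- nodes[sort_c(names(nodes))]
  edges <- edges[sort_c(names(edges))]
  structure(list(
    nodes = nodes,
    edges = edges,
    provenance = list(
      nodes_source = nodes_source, edges_source = edges_source,
      dialect = c(nodes = ndialect, edges = edialect),
      loaded_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
      warnings = warnings,
      list_delimiter = list_delimiter,
      equivalent_identifiers_property = equivalent_identifiers_property
    )
  ), class = "kg_graph")
}

fetch_source <- function(source, cache_dir = NULL) {
  if (!grepl("^https?://", source)) {
    if (!file.exists(source)) {
      stop_onehop("onehop_io_error", "source not found: %s", source)
    }
    return(source)
  }
  cache_dir <- cache_dir %||% file.path(tempdir(), "onehop-cache")
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  dest <- file.path(cache_dir, paste0(
    digest::digest(source, algo = "sha1", serialize = FALSE), "-", basename(source)))
  if (!file.exists(dest)) {
    ok <- tryCatch(utils::download.file(source, dest, quiet = TRUE) == 0L,
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop_onehop("onehop_io_error", "could not fetch source: %s", source)
  }
  dest
}

sniff_dialect <- function(path) {
  if (grepl("\\.(jsonl|jsonlines|ndjson)$", path, ignore.case = TRUE)) return("jsonlines")
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) return("tsv")
  con <- file(path, "rb"); on.exit(close(con))
  first <- readChar(con, 1L, useBytes = TRUE)
  if (identical(first, "{")) "jsonlines" else "tsv"
}

# Read one KGX file into a list of flat records (named lists; multi-valued
# fields already lists of character).
read_kgx_records <- function(path, dialect, list_delimiter) {
  if (dialect == "jsonlines") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    return(lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                      error = function(e) NULL)
      if (is.null(rec)) {
        stop_onehop("onehop_format_error", "%s: line %d is not valid JSON", path, i)
      }
      rec
    }))
  }
  dt <- tryCatch(
    data.table::fread(path, sep = "\t", colClasses = "character", quote = "",
                      header = TRUE, na.strings = NULL, fill = TRUE,
                      showProgress = FALSE),
    error = function(e) {
      stop_onehop("onehop_format_error", "%s: cannot parse as KGX TSV (%s)",
                  path, conditionMessage(e))
    })
  cols <- names(dt)
  lapply(seq_len(nrow(dt)), function(i) {
    rec <- as.list(dt[i])
    for (col in cols) {
      if (col %in% ALWAYS_LIST_FIELDS || grepl(list_delimiter, rec[[col]], fixed = TRUE)) {
        rec[[col]] <- parse_list_field(rec[[col]], "tsv", list_delimiter)
      }
    }
    rec
  })
}

# KGX fields that are list-valued by convention even when holding 0-1 items.
ALWAYS_LIST_FIELDS <- c("category", "categories", "equivalent_identifiers",
                        "publications")

as_knowledge_node <- function(rec, eq_prop, root_category) {
  cats <- norm_name(as.character(unlist(rec$category %||% rec$categories)))
  cats <- cats[nzchar(cats)]
  if (length(cats) == 0L) cats <- norm_name(root_category)
  eq <- as.character(unlist(rec[[eq_prop]]))
  eq <- eq[nzchar(eq)]
  props <- rec[setdiff(names(rec), c("id", "name", "category", "categories", eq_prop))]
  props <- props[vapply(props, function(v) length(v) > 0L && any(nzchar(as.character(v))),
                        logical(1))]
  list(id = rec$id, name = rec$name %||% "", categories = cats,
       equivalent_identifiers = eq, properties = props)
}

as_knowledge_edge <- function(rec) {
  props <- rec[setdiff(names(rec), c("id", "subject", "predicate", "object"))]
  props <- props[vapply(props, function(v) length(v) > 0L && any(nzchar(as.character(v))),
                        logical(1))]
  list(id = as.character(rec$id %||% ""), subject = rec$subject,
       object = rec$object, predicate = norm_name(rec$predicate),
       properties = props)
}

#' Parse a multi-valued KGX field
#'
#' In the JSON Lines dialect arrays pass through natively; in the TSV dialect
#' the raw string is split on the delimiter, items are whitespace-trimmed and
#' empties dropped.
#'
#' @param raw Raw field value (character scalar for TSV, anything for JSON Lines).
#' @param dialect `"tsv"` or `"jsonlines"`.
#' @param delimiter TSV list separator.
#' @return Character vector (possibly empty).
#' @export
parse_list_field <- function(raw, dialect = c("tsv", "jsonlines"), delimiter = "|") {
  dialect <- match.arg(dialect)
  if (dialect == "jsonlines") {
    out <- as.character(unlist(raw))
    return(out[nzchar(out)])
  }
  if (is.null(raw) || length(raw) == 0L) return(character(0))
  parts <- trimws(strsplit(as.character(raw), delimiter, fixed = TRUE)[[1]])
  parts[nzchar(parts)]
}

#' Write a knowledge graph to KGX flat files
#'
#' Serializes a `kg_graph` in either KGX dialect such that
#' [read_graph()] on the output reproduces the graph (node and edge sets and
#' their properties). In the TSV dialect, multi-valued fields are joined with
#' the list delimiter.
#'
#' @param graph A `kg_graph`.
#' @param nodes_target,edges_target Output file paths.
#' @param dialect `"tsv"` or `"jsonlines"`.
#' @param list_delimiter TSV list separator.
#' @export
write_graph <- function(graph, nodes_target, edges_target,
                        dialect = c("tsv", "jsonlines"), list_delimiter = "|") {
  dialect <- match.arg(dialect)
  eq_prop <- graph$provenance$equivalent_identifiers_property %||% "equivalent_identifiers"
  nrecs <- lapply(graph$nodes, function(n) {
    rec <- c(list(id = n$id, name = n$name, category = emit_name(n$categories)),
             setNames(list(n$equivalent_identifiers), eq_prop), n$properties)
    rec[[eq_prop]] <- n$equivalent_identifiers
    rec
  })
  erecs <- lapply(graph$edges, function(e) {
    c(list(id = e$id, subject = e$subject, predicate = emit_name(e$predicate),
           object = e$object), e$properties)
  })
  if (dialect == "jsonlines") {
    write_jsonl(nrecs, nodes_target)
    write_jsonl(erecs, edges_target)
  } else {
    write_kgx_tsv(nrecs, nodes_target, c("id", "name", "category", eq_prop), list_delimiter)
    write_kgx_tsv(erecs, edges_target, c("id", "subject", "predicate", "object"),
                  list_delimiter)
  }
  invisible(NULL)
}

write_jsonl <- function(recs, path) {
  lines <- vapply(recs, function(r) {
    r <- r[vapply(r, function(v) length(v) > 0L, logical(1))]
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, null = "null"))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
}

write_kgx_tsv <- function(recs, path, lead_cols, delimiter) {
  all_cols <- unique(c(lead_cols, unlist(lapply(recs, names))))
  rows <- lapply(recs, function(r) {
    vapply(all_cols, function(col) {
      v <- r[[col]]
      if (is.null(v)) "" else paste(as.character(v), collapse = delimiter)
    }, character(1))
  })
  dt <- if (length(rows)) {
    data.table::setDT(as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE))
  } else {
    data.table::setDT(setNames(replicate(length(all_cols), character(0), simplify = FALSE),
                               all_cols))
  }
  data.table::setnames(dt, all_cols)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(NULL)
}

# Structural equality of two graphs, ignoring provenance. Used by tests and
# the round-trip contract.
graph_equal <- function(g1, g2) {
  norm <- function(g) {
    list(
      nodes = lapply(g$nodes, function(n) {
        n$properties <- normalize_props(n$properties)
        n[c("id", "name", "categories", "equivalent_identifiers", "properties")]
      }),
      edges = lapply(g$edges, function(e) {
        e$properties <- normalize_props(e$properties)
        e[c("id", "subject", "object", "predicate", "properties")]
      })
    )
  }
  isTRUE(all.equal(norm(g1), norm(g2), check.attributes = FALSE))
}

normalize_props <- function(props) {
  if (length(props) == 0L) return(list())
  props <- props[sort_c(names(props))]
  lapply(props, function(v) as.character(unlist(v)))
}

#' @export
print.kg_graph <- function(x, ...) {
  w <- x$provenance$warnings
  cat(sprintf("<kg_graph> %d nodes, %d edges\n", length(x$nodes), length(x$edges)))
  if (!is.null(w) && (w$dangling_edges > 0L || w$duplicate_nodes > 0L)) {
    cat(sprintf("  load warnings: %d dangling edges dropped, %d duplicate nodes\n",
                w$dangling_edges, w$duplicate_nodes))
  }
  invisible(x)
}
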