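# Synthetic KGX graph generator with controlled hierarchy, equivalence and
# subclass structure. The generator is first-class tooling: it defines the
# conditions under which the engine's reasoning is validated, and emits its
# ground truth alongside the files.

#' Specification for a synthetic knowledge graph
#'
#' @param n_nodes,n_edges Non-negative counts (edges excludes planted
#'   subclass edges).
#' @param category_tree_depth,predicate_tree_depth Hierarchy depths below
#'   the root (small integers).
#' @param symmetric_fraction Fraction of generated predicates declared
#'   symmetric.
#' @param inverse_pair_fraction Fraction of generated predicate slots that
#'   become inverse pairs (one canonical member each).
#' @param equivalence_cluster_rate Fraction of nodes planted into
#'   equivalence clusters of size 2--3 via `equivalent_identifiers`.
#' @param subclass_chain_count,subclass_chain_length Number and length of
#'   planted `subclass_of` chains.
#' @param seed Integer; a fixed seed makes [generate_kg()] byte-identical
#'   across runs.
#' @return A validated `synth_spec` list.
#' @export
synth_spec <- function(n_nodes = 50L, n_edges = 200L,
                       category_tree_depth = 2L, predicate_tree_depth = 2L,
                       symmetric_fraction = 0.25, inverse_pair_fraction = 0.25,
                       equivalence_cluster_rate = 0.1,
                       subclass_chain_count = 2L, subclass_chain_length = 3L,
                       seed = 1L) {
  spec <- list(n_nodes = as.integer(n_nodes), n_edges = as.integer(n_edges),
               category_tree_depth = as.integer(category_tree_depth),
               predicate_tree_depth = as.integer(predicate_tree_depth),
               symmetric_fraction = symmetric_fraction,
               inverse_pair_fraction = inverse_pair_fraction,
               equivalence_cluster_rate = equivalence_cluster_rate,
               subclass_chain_count = as.integer(subclass_chain_count),
               subclass_chain_length = as.integer(subclass_chain_length),
               seed = as.integer(seed))
  for (f in c("symmetric_fraction", "inverse_pair_fraction", "equivalence_cluster_rate")) {
    if (spec[[f]] < 0 || spec[[f]] > 1) {
      stop_onehop("onehop_config_error", "%s must be in [0, 1]", f)
    }
  }
  for (f in c("n_nodes", "n_edges", "category_tree_depth", "predicate_tree_depth",
              "subclass_chain_count", "subclass_chain_length")) {
    if (is.na(spec[[f]]) || spec[[f]] < 0L) {
      stop_onehop("onehop_config_error", "%s must be a non-negative integer", f)
    }
  }
  if (spec$subclass_chain_count * spec$subclass_chain_length > spec$n_nodes) {
    stop_onehop("onehop_config_error",
                "infeasible spec: %d subclass chains of length %d exceed %d nodes",
                spec$subclass_chain_count, spec$subclass_chain_length, spec$n_nodes)
  }
  if (spec$n_nodes == 0L && spec$n_edges > 0L) {
    stop_onehop("onehop_config_error", "cannot draw edges over zero nodes")
  }
  structure(spec, class = "synth_spec")
}

# One pseudo-random sub-stream per purpose, derived from the single seed, so
# adding a generation phase does not perturb earlier draws.
stream_seed <- function(seed, purpose) {
  h <- digest::digest(paste0(seed, "\x1f", purpose), algo = "sha1", serialize = FALSE)
  strtoi(substr(h, 1L, 7L), base = 16L)
}

with_stream <- function(seed, purpose, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(stream_seed(seed, purpose))
  expr
}

#' Generate a synthetic knowledge graph with ground truth
#'
#' Emits a matching semantic-model schema, the graph in both KGX dialects,
#' and a ground-truth JSON file describing the planted structures. Category
#' and predicate hierarchies are random DAGs of the requested depths (each
#' non-root name draws 1--2 parents from the level above); edges are drawn
#' uniformly over node pairs with predicates drawn over the generated
#' predicate set; equivalence clusters are planted through
#' `equivalent_identifiers`; subclass chains are planted as `subclass_of`
#' edges. Generated CURIEs use the reserved `TEST:` prefix.
#'
#' @param spec A [synth_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the emitted file paths (`model`,
#'   `nodes_tsv`, `edges_tsv`, `nodes_jsonl`, `edges_jsonl`,
#'   `ground_truth_path`) and the `ground_truth` list itself.
#' @export
generate_kg <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synth_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  model_def <- with_stream(spec$seed, "hierarchies", synth_model_def(spec))
  model_path <- file.path(out_dir, "model.yaml")
  yaml::write_yaml(model_def, model_path)

  n <- spec$n_nodes
  node_ids <- if (n > 0L) sprintf("TEST:n%04d", seq_len(n)) else character(0)

  node_cats <- with_stream(spec$seed, "node-categories", {
    leafish <- setdiff(names(model_def$categories), "Thing")
    if (length(leafish) == 0L) leafish <- "Thing"
    lapply(seq_len(n), function(i) {
      k <- sample(1:2, 1L)
      unique(sample(leafish, min(k, length(leafish))))
    })
  })

  clusters <- with_stream(spec$seed, "equivalence-clusters", {
    n_clustered <- floor(spec$equivalence_cluster_rate * n)
    pool <- if (n_clustered >= 2L) sample(node_ids, n_clustered) else character(0)
    cl <- list()
    while (length(pool) >= 2L) {
      size <- min(sample(2:3, 1L), length(pool))
      cl[[length(cl) + 1L]] <- sort_c(pool[seq_len(size)])
      pool <- pool[-seq_len(size)]
    }
    cl
  })
  eq_of <- list()
  for (cl in clusters) for (m in cl) eq_of[[m]] <- setdiff(cl, m)

  chains <- with_stream(spec$seed, "subclass-chains", {
    need <- spec$subclass_chain_count * spec$subclass_chain_length
    picked <- if (need > 0L) sample(node_ids, need) else character(0)
    if (spec$subclass_chain_count > 0L) {
      split(picked, rep(seq_len(spec$subclass_chain_count),
                        each = spec$subclass_chain_length))
    } else list()
  })
  subclass_edges <- list()
  for (chain in chains) {
    # chain[1] is the top concept; each later node is a subclass of its
    # predecessor
    if (length(chain) >= 2L) {
      for (i in 2:length(chain)) {
        subclass_edges[[length(subclass_edges) + 1L]] <-
          list(subject = chain[[i]], predicate = "subclass_of", object = chain[[i - 1L]])
      }
    }
  }

  random_edges <- with_stream(spec$seed, "edges", {
    preds <- setdiff(names(model_def$predicates), c("related_to", "subclass_of"))
    if (length(preds) == 0L) preds <- "related_to"
    lapply(seq_len(spec$n_edges), function(i) {
      list(subject = sample(node_ids, 1L), object = sample(node_ids, 1L),
           predicate = sample(preds, 1L),
           publications = if (stats::runif(1) < 0.5) {
             sprintf("PMID:%d", sample(1e6L, sample(1:3, 1L)))
           } else NULL,
           score = sprintf("%.3f", stats::runif(1)))
    })
  })

  nodes <- setNames(lapply(seq_len(n), function(i) {
    list(id = node_ids[[i]], name = sprintf("test node %d", i),
         categories = node_cats[[i]],
         equivalent_identifiers = eq_of[[node_ids[[i]]]] %||% character(0),
         properties = list())
  }), node_ids)

  all_edges <- c(
    lapply(seq_along(random_edges), function(i) {
      e <- random_edges[[i]]
      props <- list(primary_knowledge_source = "infores:synth", score = e$score)
      if (!is.null(e$publications)) props$publications <- e$publications
      list(id = sprintf("e%05d", i), subject = e$subject, object = e$object,
           predicate = e$predicate, properties = props)
    }),
    lapply(seq_along(subclass_edges), function(i) {
      s <- subclass_edges[[i]]
      list(id = sprintf("sc%04d", i), subject = s$subject, object = s$object,
           predicate = s$predicate,
           properties = list(primary_knowledge_source = "infores:synth-ontology"))
    })
  )
  edges <- setNames(all_edges, vapply(all_edges, `[[`, character(1), "id"))

  graph <- structure(list(
    nodes = nodes[sort_c(names(nodes))],
    edges = edges[sort_c(names(edges))],
    provenance = list(equivalent_identifiers_property = "equivalent_identifiers",
                      warnings = list())
  ), class = "kg_graph")

  paths <- list(
    model = model_path,
    nodes_tsv = file.path(out_dir, "nodes.tsv"),
    edges_tsv = file.path(out_dir, "edges.tsv"),
    nodes_jsonl = file.path(out_dir, "nodes.jsonl"),
    edges_jsonl = file.path(out_dir, "edges.jsonl"),
    ground_truth_path = file.path(out_dir, "ground_truth.json"))
  write_graph(graph, paths$nodes_tsv, paths$edges_tsv, dialect = "tsv")
  write_graph(graph, paths$nodes_jsonl, paths$edges_jsonl, dialect = "jsonlines")

  ground_truth <- list(
    spec = unclass(spec),
    model = model_def,
    clusters = clusters,
    subclass_edges = subclass_edges,
    edge_ids = sort_c(names(edges)))
  jsonlite::write_json(ground_truth, paths$ground_truth_path, auto_unbox = TRUE,
                       null = "null", digits = NA, pretty = TRUE)

  invisible(c(paths, list(ground_truth = ground_truth, graph = graph)))
}

# Random category/predicate hierarchy definitions in the schema-file shape.
synth_model_def <- function(spec) {
  categories <- list(Thing = list())
  prev <- "Thing"
  for (d in seq_len(spec$category_tree_depth)) {
    level <- sprintf("Cat%d_%d", d, 1:3)
    for (nm in level) {
      k <- min(sample(1:2, 1L), length(prev))
      categories[[nm]] <- list(parents = sort_c(sample(prev, k)))
    }
    prev <- level
  }

  predicates <- list(related_to = list(symmetric = TRUE))
  prev <- "related_to"
  for (d in seq_len(spec$predicate_tree_depth)) {
    level_names <- character(0)
    for (i in 1:3) {
      k <- min(sample(1:2, 1L), length(prev))
      parents <- sort_c(sample(prev, k))
      u <- stats::runif(1)
      base <- sprintf("pred%d_%d", d, i)
      if (u < spec$symmetric_fraction) {
        predicates[[base]] <- list(parents = parents, symmetric = TRUE)
        level_names <- c(level_names, base)
      } else if (u < spec$symmetric_fraction + spec$inverse_pair_fraction) {
        inv <- paste0(base, "_rev")
        predicates[[base]] <- list(parents = parents, canonical = TRUE, inverse = inv)
        predicates[[inv]] <- list(parents = "related_to", inverse = base)
        level_names <- c(level_names, base)
      } else {
        predicates[[base]] <- list(parents = parents)
        level_names <- c(level_names, base)
      }
    }
    prev <- level_names
  }
  predicates$subclass_of <- list(parents = "related_to")

  list(categories = categories, predicates = predicates,
       category_prefixes = list(Thing = list("TEST")))
}
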