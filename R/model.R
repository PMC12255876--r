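#' Load a semantic model from a schema file
#'
#' The semantic model is the reasoning substrate for the engine: the category
#' and predicate hierarchies (directed acyclic graphs, multiple parents
#' allowed) plus per-predicate symmetry, inverse, and canonical-direction
#' flags, in the style of the Biolink Model. The schema dialect is a flat
#' YAML or JSON mapping with top-level keys `categories`, `predicates` and
#' (optionally) `category_prefixes`; each category record may carry
#' `parents`, each predicate record `parents`, `symmetric`, `inverse` and
#' `canonical`. A full Biolink release maps onto this dialect by exporting,
#' for every class and predicate slot, its `is_a`/mixin parents and the
#' `symmetric`, `inverse` and `canonical_predicate` slot annotations.
#'
#' Names are accepted with or without the `biolink:` prefix and compared
#' case-sensitively on the bare form; TRAPI-facing output re-attaches the
#' prefix. Descendant and ancestor sets of every name are precomputed at
#' load time so hierarchy reasoning is a table lookup afterwards.
#'
#' Validation is strict and failures are fatal: dangling parent or inverse
#' references, cycles in either hierarchy, symmetric predicates declaring an
#' inverse, non-reciprocal inverse pairs, and inverse pairs without exactly
#' one canonical member are all schema errors.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` schema file.
#' @return An object of class `semantic_model`.
#' @export
load_semantic_model <- function(path) {
  if (!file.exists(path)) {
    stop_onehop("onehop_io_error", "semantic model file not found: %s", path)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw) || is.null(raw$categories) || is.null(raw$predicates)) {
    stop_onehop("onehop_schema_error",
                "schema file %s must define 'categories' and 'predicates'", path)
  }

  categories <- normalize_hierarchy(raw$categories, "category")
  predicates <- normalize_hierarchy(raw$predicates, "predicate")

  # predicate flags, with defaults: not symmetric; canonical unless declared
  # otherwise or the non-canonical member of an inverse pair
  for (nm in names(predicates)) {
    rec <- raw$predicates[[which(norm_name(names(raw$predicates)) == nm)]]
    predicates[[nm]]$symmetric <- isTRUE(rec$symmetric)
    inv <- rec$inverse
    predicates[[nm]]$inverse <- if (is.null(inv) || !nzchar(inv)) NA_character_ else norm_name(inv)
    predicates[[nm]]$canonical <- if (is.null(rec$canonical)) NA else isTRUE(rec$canonical)
  }
  validate_inverse_pairs(predicates)
  for (nm in names(predicates)) {
    if (is.na(predicates[[nm]]$canonical)) {
      # undeclared: canonical iff not the non-canonical member of an inverse
      # pair (predicates without an inverse are stored as-is)
      predicates[[nm]]$canonical <- is.na(predicates[[nm]]$inverse)
    }
  }

  root_category <- find_root(categories, "category")
  root_predicate <- find_root(predicates, "predicate")

  prefixes <- list()
  if (!is.null(raw$category_prefixes)) {
    prefixes <- raw$category_prefixes
    names(prefixes) <- norm_name(names(prefixes))
    bad <- setdiff(names(prefixes), names(categories))
    if (length(bad)) {
      stop_onehop("onehop_schema_error",
                  "category_prefixes references unknown category: %s", bad[[1L]])
    }
    prefixes <- lapply(prefixes, function(p) as.character(unlist(p)))
  }

  model <- structure(list(
    categories = categories,
    predicates = predicates,
    category_prefixes = prefixes,
    root_category = root_category,
    root_predicate = root_predicate
  ), class = "semantic_model")

  model$cat_desc  <- closure_sets(categories, down = TRUE)
  model$cat_anc   <- closure_sets(categories, down = FALSE)
  model$pred_desc <- closure_sets(predicates, down = TRUE)
  model$pred_anc  <- closure_sets(predicates, down = FALSE)
  model$checksum  <- digest::digest(list(categories, predicates, prefixes))
  model
}

# Coerce a raw names -> record mapping into {parents: chr} records with
# normalized names, verifying parent references and acyclicity.
normalize_hierarchy <- function(raw, what) {
  if (length(raw) == 0L) {
    stop_onehop("onehop_schema_error", "schema declares no %s entries", what)
  }
  nms <- norm_name(names(raw))
  if (anyDuplicated(nms)) {
    stop_onehop("onehop_schema_error", "duplicate %s name: %s", what,
                nms[duplicated(nms)][[1L]])
  }
  out <- setNames(vector("list", length(nms)), nms)
  for (i in seq_along(nms)) {
    rec <- raw[[i]]
    parents <- if (is.list(rec) || is.character(rec)) {
      if (is.character(rec)) rec else as.character(unlist(rec$parents))
    } else character(0)
    out[[i]] <- list(parents = norm_name(parents))
  }
  for (nm in nms) {
    missing <- setdiff(out[[nm]]$parents, nms)
    if (length(missing)) {
      stop_onehop("onehop_schema_error",
                  "%s '%s' lists unknown parent '%s'", what, nm, missing[[1L]])
    }
  }
  cyc <- find_cycle(out)
  if (!is.null(cyc)) {
    stop_onehop("onehop_schema_error", "%s hierarchy contains a cycle: %s",
                what, paste(cyc, collapse = " -> "))
  }
  out
}

# DFS cycle detection; returns one cycle as a name vector, or NULL.
find_cycle <- function(h) {
  state <- setNames(integer(length(h)), names(h))  # 0 new, 1 in-stack, 2 done
  stack <- character(0)
  found <- NULL
  visit <- function(nm) {
    if (!is.null(found)) return()
    if (state[[nm]] == 1L) {
      i <- match(nm, stack)
      found <<- c(stack[i:length(stack)], nm)
      return()
    }
    if (state[[nm]] == 2L) return()
    state[[nm]] <<- 1L
    stack <<- c(stack, nm)
    for (p in h[[nm]]$parents) visit(p)
    stack <<- stack[-length(stack)]
    state[[nm]] <<- 2L
  }
  for (nm in names(h)) visit(nm)
  found
}

find_root <- function(h, what) {
  roots <- names(h)[vapply(h, function(r) length(r$parents) == 0L, logical(1))]
  if (length(roots) != 1L) {
    stop_onehop("onehop_schema_error",
                "%s hierarchy must have exactly one root, found %d (%s)",
                what, length(roots), paste(roots, collapse = ", "))
  }
  roots
}

validate_inverse_pairs <- function(predicates) {
  for (nm in names(predicates)) {
    rec <- predicates[[nm]]
    if (is.na(rec$inverse)) next
    if (rec$symmetric) {
      stop_onehop("onehop_schema_error",
                  "symmetric predicate '%s' must not declare an inverse", nm)
    }
    q <- rec$inverse
    if (!q %in% names(predicates)) {
      stop_onehop("onehop_schema_error",
                  "predicate '%s' declares unknown inverse '%s'", nm, q)
    }
    if (identical(q, nm)) {
      stop_onehop("onehop_schema_error",
                  "predicate '%s' declares itself as inverse; use symmetric instead", nm)
    }
    back <- predicates[[q]]$inverse
    if (is.na(back) || !identical(back, nm)) {
      stop_onehop("onehop_schema_error",
                  "inverse pair (%s, %s) is not reciprocal", nm, q)
    }
    canon <- c(isTRUE(predicates[[nm]]$canonical), isTRUE(predicates[[q]]$canonical))
    if (sum(canon) != 1L) {
      stop_onehop("onehop_schema_error",
                  "inverse pair (%s, %s) must have exactly one canonical member", nm, q)
    }
  }
  invisible(TRUE)
}

# Inclusive transitive closure for every name: descendant sets (down = TRUE)
# or ancestor sets. Memoized DAG walk over the child adjacency.
closure_sets <- function(h, down = TRUE) {
  nms <- names(h)
  if (down) {
    children <- setNames(lapply(nms, function(x) character(0)), nms)
    for (nm in nms) for (p in h[[nm]]$parents) children[[p]] <- c(children[[p]], nm)
    adj <- children
  } else {
    adj <- lapply(h, function(r) r$parents)
  }
  memo <- new.env(parent = emptyenv())
  walk <- function(nm) {
    if (!is.null(memo[[nm]])) return(memo[[nm]])
    out <- nm
    for (nxt in adj[[nm]]) out <- c(out, walk(nxt))
    out <- unique(out)
    memo[[nm]] <- out
    out
  }
  setNames(lapply(nms, walk), nms)
}

check_known <- function(model, name, map, what) {
  nm <- norm_name(name)
  if (!nm %in% names(map)) {
    stop_onehop("onehop_unknown_name", "unknown %s: '%s'", what, name)
  }
  nm
}

#' Inclusive descendant set of a category
#'
#' Returns the category itself plus every category whose ancestor chain
#' reaches it, using the closure precomputed at load time.
#'
#' @param model A `semantic_model`.
#' @param category Category name (bare or `biolink:`-prefixed).
#' @return Character vector of bare category names.
#' @export
category_descendants <- function(model, category) {
  nm <- check_known(model, category, model$categories, "category")
  model$cat_desc[[nm]]
}

#' Inclusive descendant set of a predicate
#'
#' @param model A `semantic_model`.
#' @param predicate Predicate name (bare or `biolink:`-prefixed).
#' @return Character vector of bare predicate names.
#' @export
predicate_descendants <- function(model, predicate) {
  nm <- check_known(model, predicate, model$predicates, "predicate")
  model$pred_desc[[nm]]
}

#' Canonical storage form of a predicate
#'
#' Edges are stored under the canonical member of each inverse predicate
#' pair. For a canonical or symmetric predicate this is the identity; for
#' the non-canonical member it returns the inverse together with
#' `flipped = TRUE`, signalling that subject and object swap.
#'
#' @param model A `semantic_model`.
#' @param predicate Predicate name.
#' @return List with elements `predicate` (bare name) and `flipped` (logical).
#' @export
canonical_form <- function(model, predicate) {
  nm <- check_known(model, predicate, model$predicates, "predicate")
  rec <- model$predicates[[nm]]
  if (rec$symmetric || isTRUE(rec$canonical)) {
    list(predicate = nm, flipped = FALSE)
  } else {
    list(predicate = rec$inverse, flipped = TRUE)
  }
}

#' Is a predicate symmetric?
#'
#' @param model A `semantic_model`.
#' @param predicate Predicate name.
#' @return Logical flag as declared in the schema.
#' @export
is_symmetric <- function(model, predicate) {
  nm <- check_known(model, predicate, model$predicates, "predicate")
  model$predicates[[nm]]$symmetric
}

#' @export
print.semantic_model <- function(x, ...) {
  cat(sprintf("<semantic_model> %d categories (root: %s), %d predicates (root: %s)\n",
              length(x$categories), x$root_category,
              length(x$predicates), x$root_predicate))
  n_sym <- sum(vapply(x$predicates, `[[`, logical(1), "symmetric"))
  n_inv <- sum(!is.na(vapply(x$predicates, `[[`, character(1), "inverse")))
  cat(sprintf("  %d symmetric predicates, %d inverse-pair members\n", n_sym, n_inv))
  invisible(x)
}
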