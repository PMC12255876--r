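# The web-facing layer: one or more indexed KGs served at separate
# sub-endpoints from shared read-only state. The routing core
# (handle_request) is a pure function from (state, route, method, body) to
# an HTTP-shaped response; serve_http() is a thin socket runner over it.

#' Load per-knowledge-graph service configurations
#'
#' Reads every `*.json` file in a directory as one `ServiceConfig`.
#' Required slots: `nodes_file`, `edges_file`, `endpoint_name`,
#' `semantic_model`. Optional slots: `canonicalize` (flag),
#' `trapi_attribute_map`, `subclass_sources`, `subclass_predicates`,
#' `preferred_prefix_order`, `list_delimiter`,
#' `equivalent_identifiers_property`, `resolver_stub`,
#' `rebuild_token_hash` (sha-256 hex of the accepted token). Endpoint names
#' must be URL-safe and unique across the directory; violations are fatal
#' configuration errors.
#'
#' @param config_dir Directory containing at least one config file.
#' @return List of validated config lists (class `service_config`).
#' @export
load_configs <- function(config_dir) {
  files <- sort_c(list.files(config_dir, pattern = "\\.json$", full.names = TRUE))
  if (length(files) == 0L) {
    stop_onehop("onehop_config_error", "no config files (*.json) in %s", config_dir)
  }
  configs <- lapply(files, function(f) {
    cfg <- tryCatch(jsonlite::fromJSON(f, simplifyVector = FALSE),
                    error = function(e) NULL)
    if (is.null(cfg)) {
      stop_onehop("onehop_config_error", "config file %s is not valid JSON", f)
    }
    for (slot in c("nodes_file", "edges_file", "endpoint_name", "semantic_model")) {
      if (is.null(cfg[[slot]]) || !nzchar(cfg[[slot]])) {
        stop_onehop("onehop_config_error", "config file %s lacks required slot '%s'",
                    f, slot)
      }
    }
    if (!grepl("^[A-Za-z0-9_-]+$", cfg$endpoint_name)) {
      stop_onehop("onehop_config_error",
                  "config file %s: endpoint_name '%s' is not URL-safe",
                  f, cfg$endpoint_name)
    }
    # paths are resolved relative to the config file's own directory
    for (slot in c("nodes_file", "edges_file", "semantic_model", "resolver_stub")) {
      v <- cfg[[slot]]
      if (!is.null(v) && !grepl("^(https?://|/)", v)) {
        cfg[[slot]] <- file.path(dirname(f), v)
      }
    }
    if (!is.null(cfg$subclass_sources)) {
      cfg$subclass_sources <- lapply(cfg$subclass_sources, function(v) {
        if (!grepl("^(https?://|/)", v)) file.path(dirname(f), v) else v
      })
    }
    cfg$config_path <- f
    structure(cfg, class = "service_config")
  })
  names(configs) <- vapply(configs, `[[`, character(1), "endpoint_name")
  dup <- names(configs)[duplicated(names(configs))]
  if (length(dup)) {
    stop_onehop("onehop_config_error", "duplicate endpoint_name '%s'", dup[[1L]])
  }
  configs
}

# Full pipeline for one endpoint: read -> equivalence -> (optional)
# canonicalize -> index -> subclass closure -> meta-KG -> test triples.
build_endpoint <- function(cfg, snapshot_dir = NULL, log = NULL) {
  model <- load_semantic_model(cfg$semantic_model)
  snap <- if (!is.null(snapshot_dir)) file.path(snapshot_dir, cfg$endpoint_name)

  loaded <- NULL
  if (!is.null(snap) && dir.exists(snap)) {
    loaded <- tryCatch({
      parts <- load_index(snap)
      if (!identical(parts$index$build_meta$model_checksum, model$checksum)) {
        log_msg(log, "INFO", "[%s] snapshot model checksum mismatch; rebuilding",
                cfg$endpoint_name)
        NULL
      } else parts
    }, onehop_error = function(e) {
      log_msg(log, "WARN", "[%s] snapshot unusable (%s); rebuilding",
              cfg$endpoint_name, conditionMessage(e))
      NULL
    })
  }

  if (is.null(loaded)) {
    graph <- read_graph(
      cfg$nodes_file, cfg$edges_file, dialect = cfg$dialect %||% "auto",
      list_delimiter = cfg$list_delimiter %||% "|",
      equivalent_identifiers_property =
        cfg$equivalent_identifiers_property %||% "equivalent_identifiers",
      root_category = model$root_category, log = log)
    resolver <- if (!is.null(cfg$resolver_stub)) file_resolver(cfg$resolver_stub)
    eqmap <- build_equivalence_map(
      graph, resolver,
      prefix_priority = as.character(unlist(cfg$preferred_prefix_order)), log = log)
    if (isTRUE(cfg$canonicalize)) graph <- canonicalize_graph(graph, eqmap)
    ext_edges <- NULL
    if (length(cfg$subclass_sources)) {
      recs <- unlist(lapply(cfg$subclass_sources, function(src) {
        path <- fetch_source(src)
        read_kgx_records(path, sniff_dialect(path), cfg$list_delimiter %||% "|")
      }), recursive = FALSE)
      ext_edges <- data.frame(
        subject = vapply(recs, function(r) as.character(r$subject %||% ""), character(1)),
        predicate = norm_name(vapply(recs, function(r) as.character(r$predicate %||% ""),
                                     character(1))),
        object = vapply(recs, function(r) as.character(r$object %||% ""), character(1)),
        stringsAsFactors = FALSE)
    }
    subclass <- build_subclass_closure(
      graph, ext_edges,
      subclass_predicates = as.character(unlist(cfg$subclass_predicates %||% "subclass_of")),
      log = log)
    index <- build_index(graph, model, options = list(canonicalize = isTRUE(cfg$canonicalize)),
                         log = log)
    if (!is.null(snap)) save_index(index, subclass, eqmap, snap)
    log_msg(log, "INFO", "[%s] built index: %d nodes, %d edges", cfg$endpoint_name,
            length(index$node_store), length(index$edge_store))
  } else {
    index <- loaded$index; subclass <- loaded$subclass; eqmap <- loaded$eqmap
    log_msg(log, "INFO", "[%s] loaded snapshot: %d nodes, %d edges", cfg$endpoint_name,
            length(index$node_store), length(index$edge_store))
  }

  metakg <- build_meta_kg(index, model)
  triples <- build_test_triples(index, metakg, seed = cfg$test_triple_seed %||% 0L)
  list(config = cfg, model = model, index = index, subclass = subclass,
       eqmap = eqmap, metakg = metakg, test_triples = triples,
       status = "ok", error = NULL)
}

#' Build the full service state
#'
#' Builds (or restores from snapshot) every configured endpoint. A failing
#' endpoint is marked `failed` and reported by the healthcheck while the
#' remaining endpoints still serve. The returned state is an environment so
#' a rebuild can atomically swap the endpoint table under concurrent
#' readers.
#'
#' @param configs List from [load_configs()] (or a single config).
#' @param snapshot_dir Optional directory for per-endpoint index snapshots.
#' @return An environment of class `service_state`.
#' @export
build_service <- function(configs, snapshot_dir = NULL) {
  if (inherits(configs, "service_config")) configs <- list(configs)
  state <- new.env(parent = emptyenv())
  class(state) <- "service_state"
  state$log <- new_log()
  state$snapshot_dir <- snapshot_dir
  state$configs <- configs
  state$code_version <- as.character(utils::packageVersion("onehop"))
  state$started_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  state$rebuilding <- FALSE
  state$endpoints <- build_all_endpoints(configs, snapshot_dir, state$log)
  state
}

build_all_endpoints <- function(configs, snapshot_dir, log) {
  endpoints <- list()
  for (cfg in configs) {
    endpoints[[cfg$endpoint_name]] <- tryCatch(
      build_endpoint(cfg, snapshot_dir, log),
      error = function(e) {
        log_msg(log, "ERROR", "[%s] build failed: %s", cfg$endpoint_name,
                conditionMessage(e))
        list(config = cfg, status = "failed", error = conditionMessage(e))
      })
  }
  endpoints
}

json_body <- function(obj) {
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", digits = NA))
}

http_response <- function(status, obj) {
  list(status = as.integer(status), content_type = "application/json",
       body = json_body(obj))
}

#' Route an HTTP-shaped request against the service state
#'
#' Routes: `POST /{endpoint}/query`, `GET /{endpoint}/meta_knowledge_graph`,
#' `GET /{endpoint}/sri_test_triples`, `GET /code_version`, `GET /logs`,
#' `GET /healthcheck`, `POST /rebuild` (authenticated via the
#' `x-rebuild-token` header). Query validation failures return 400 with the
#' error list; unknown routes 404; internal failures 500 with a correlation
#' id and no stack trace in the body.
#'
#' @param state A `service_state`.
#' @param route URL path (e.g. `"/kg2c/query"`).
#' @param method HTTP verb.
#' @param body Request body: JSON text or an equivalent R list.
#' @param headers Named list of request headers (lower-case names).
#' @return List with `status`, `content_type`, `body` (JSON text).
#' @export
handle_request <- function(state, route, method = "GET", body = NULL,
                           headers = list()) {
  method <- toupper(method)
  parts <- strsplit(sub("^/+", "", route), "/", fixed = TRUE)[[1L]]
  tryCatch({
    if (length(parts) == 1L && method == "GET" && parts == "code_version") {
      per_kg <- lapply(state$endpoints, function(ep) {
        if (identical(ep$status, "ok")) {
          c(list(status = "ok"), ep$index$build_meta[c("n_nodes", "n_edges")],
            list(sources = ep$index$build_meta$provenance))
        } else list(status = "failed")
      })
      return(http_response(200L, list(code_version = state$code_version,
                                      started_at = state$started_at,
                                      knowledge_graphs = per_kg)))
    }
    if (length(parts) == 1L && method == "GET" && parts == "logs") {
      return(http_response(200L, list(lines = log_tail(state$log, 500L))))
    }
    if (length(parts) == 1L && method == "GET" && parts == "healthcheck") {
      eps <- vapply(state$endpoints, function(ep) ep$status, character(1))
      all_ok <- length(eps) > 0L && all(eps == "ok")
      return(http_response(if (all_ok) 200L else 503L,
                           list(status = if (all_ok) "pass" else "fail",
                                endpoints = as.list(eps))))
    }
    if (length(parts) == 1L && method == "POST" && parts == "rebuild") {
      return(handle_rebuild(state, headers[["x-rebuild-token"]] %||% "", body))
    }
    if (length(parts) == 2L) {
      ep <- state$endpoints[[parts[[1L]]]]
      if (is.null(ep)) {
        return(http_response(404L, list(status = "NotFound",
                                        description = sprintf("no endpoint '%s'", parts[[1L]]))))
      }
      if (!identical(ep$status, "ok")) {
        return(http_response(503L, list(status = "Unavailable",
                                        description = sprintf("endpoint '%s' failed to build",
                                                              parts[[1L]]))))
      }
      if (method == "POST" && parts[[2L]] == "query") {
        return(handle_query(ep, body))
      }
      if (method == "GET" && parts[[2L]] == "meta_knowledge_graph") {
        return(http_response(200L, meta_kg_to_trapi(ep$metakg)))
      }
      if (method == "GET" && parts[[2L]] == "sri_test_triples") {
        return(http_response(200L, test_triples_to_json(ep$test_triples)))
      }
    }
    http_response(404L, list(status = "NotFound",
                             description = sprintf("no route %s %s", method, route)))
  }, onehop_constraint_error = function(e) {
    http_response(400L, list(status = "ConstraintError", description = conditionMessage(e)))
  }, onehop_unknown_name = function(e) {
    http_response(400L, list(status = "UnknownName", description = conditionMessage(e)))
  }, error = function(e) {
    cid <- substr(digest::digest(c(route, format(Sys.time(), "%H%M%OS3"))), 1L, 8L)
    log_msg(state$log, "ERROR", "[%s] internal error on %s %s: %s",
            cid, method, route, conditionMessage(e))
    http_response(500L, list(status = "InternalError",
                             description = sprintf("internal error (correlation id %s)", cid)))
  })
}

handle_query <- function(ep, body) {
  parsed <- if (is.character(body)) {
    tryCatch(jsonlite::fromJSON(body, simplifyVector = FALSE), error = function(e) NULL)
  } else body
  qg_raw <- parsed$message$query_graph
  if (is.null(qg_raw)) {
    return(http_response(400L, list(
      status = "BadRequest",
      description = "request body must be JSON with message.query_graph")))
  }
  qgraph <- trapi_query_graph(qg_raw)
  errors <- validate_query(qgraph, ep$model)
  if (length(errors)) {
    return(http_response(400L, list(status = "QueryGraphValidationError",
                                    description = "query graph is not answerable",
                                    validation_errors = errors)))
  }
  resp <- answer_query(qgraph, ep$index, ep$model, ep$subclass, ep$eqmap,
                       attribute_map = ep$config$trapi_attribute_map %||% list())
  http_response(200L, resp)
}

# TRAPI JSON query_graph -> internal query-graph list.
trapi_query_graph <- function(qg) {
  nodes <- lapply(qg$nodes, function(qn) {
    list(ids = as.character(unlist(qn$ids)),
         categories = if (is.null(qn$categories)) NULL
                      else as.character(unlist(qn$categories)))
  })
  edges <- lapply(qg$edges, function(qe) {
    list(subject = qe$subject, object = qe$object,
         predicates = if (is.null(qe$predicates)) NULL
                      else as.character(unlist(qe$predicates)),
         attribute_constraints = lapply(qe$attribute_constraints %||% list(),
                                        function(con) {
                                          list(id = con$id, operator = con$operator,
                                               value = con$value,
                                               not = isTRUE(con$not %||% con$negated))
                                        }))
  })
  list(nodes = nodes, edges = edges)
}

#' Authenticated service rebuild with atomic state swap
#'
#' Compares the sha-256 of the presented token against the configured
#' `rebuild_token_hash` (404 when no config enables the feature, 401 on
#' mismatch, 409 when a rebuild is already running). On success the whole
#' endpoint table is rebuilt from the configured sources and swapped into
#' the state in one assignment, so requests observe either the old or the
#' new state in its entirety, and 202 is returned.
#'
#' @param state A `service_state`.
#' @param token Presented rebuild token (plain text).
#' @param config_overrides Optional named list merged over each stored
#'   config before rebuilding (e.g. new `nodes_file`/`edges_file`).
#' @return HTTP-shaped response list.
#' @export
handle_rebuild <- function(state, token, config_overrides = NULL) {
  hashes <- unlist(lapply(state$configs, `[[`, "rebuild_token_hash"))
  if (length(hashes) == 0L) {
    return(http_response(404L, list(status = "NotFound",
                                    description = "rebuild is not enabled")))
  }
  presented <- digest::digest(token %||% "", algo = "sha256", serialize = FALSE)
  # fixed-length hex comparison over all configured hashes
  ok <- any(vapply(hashes, function(h) {
    a <- utf8ToInt(presented); b <- utf8ToInt(tolower(as.character(h)))
    length(a) == length(b) && sum(bitwXor(a, b)) == 0L
  }, logical(1)))
  if (!ok) {
    return(http_response(401L, list(status = "Unauthorized",
                                    description = "invalid rebuild token")))
  }
  if (isTRUE(state$rebuilding)) {
    return(http_response(409L, list(status = "Conflict",
                                    description = "a rebuild is already running")))
  }
  state$rebuilding <- TRUE
  on.exit(state$rebuilding <- FALSE)
  configs <- state$configs
  if (!is.null(config_overrides)) {
    ov <- if (is.character(config_overrides)) {
      jsonlite::fromJSON(config_overrides, simplifyVector = FALSE)
    } else config_overrides
    configs <- lapply(configs, function(cfg) {
      for (k in names(ov)) cfg[[k]] <- ov[[k]]
      cfg
    })
  }
  # stale snapshots would short-circuit the rebuild: clear them first
  if (!is.null(state$snapshot_dir)) {
    for (cfg in configs) {
      unlink(file.path(state$snapshot_dir, cfg$endpoint_name), recursive = TRUE)
    }
  }
  new_endpoints <- build_all_endpoints(configs, state$snapshot_dir, state$log)
  state$configs <- configs
  state$endpoints <- new_endpoints   # atomic swap
  log_msg(state$log, "INFO", "rebuild complete: %d endpoint(s)", length(new_endpoints))
  http_response(202L, list(status = "Accepted",
                           description = "rebuild completed and state swapped"))
}

#' Serve the state over HTTP
#'
#' Thin blocking runner over [handle_request()] using the `httpuv` package;
#' every worker shares the same read-only state. Intended for interactive
#' or scripted deployments — all routing behaviour lives in
#' [handle_request()] and is testable without sockets.
#'
#' @param state A `service_state`.
#' @param port,host Listen address.
#' @export
serve_http <- function(state, port = 8080L, host = "127.0.0.1") {
  if (!requireNamespace("httpuv", quietly = TRUE)) {
    stop_onehop("onehop_config_error", "serve_http requires the 'httpuv' package")
  }
  app <- list(call = function(req) {
    body <- tryCatch(rawToChar(req$rook.input$read()), error = function(e) "")
    hdrs <- list(`x-rebuild-token` = req$HTTP_X_REBUILD_TOKEN)
    resp <- handle_request(state, req$PATH_INFO, req$REQUEST_METHOD, body, hdrs)
    list(status = resp$status,
         headers = list("Content-Type" = resp$content_type),
         body = resp$body)
  })
  message(sprintf("onehop serving on http://%s:%d/", host, port))
  httpuv::runServer(host, port, app)
}

#' @export
print.service_state <- function(x, ...) {
  cat(sprintf("<service_state> %d endpoint(s), code version %s\n",
              length(x$endpoints), x$code_version))
  for (nm in names(x$endpoints)) {
    ep <- x$endpoints[[nm]]
    cat(sprintf("  /%s: %s\n", nm, ep$status))
  }
  invisible(x)
}
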