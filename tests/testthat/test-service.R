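# End-to-end service behaviour on the shipped demo fixture and generated KGs.

demo_state <- function(snapshot_dir = NULL) {
  cfg <- load_configs(system.file("extdata", "demo", package = "onehop"))
  build_service(cfg, snapshot_dir = snapshot_dir)
}

trapi_body <- function(qgraph) {
  jsonlite::toJSON(list(message = list(query_graph = qgraph)),
                   auto_unbox = TRUE, null = "null")
}

demo_query <- function(ids = "CHEBI:46195", categories = "biolink:Protein",
                       predicates = "biolink:interacts_with") {
  list(nodes = list(n0 = list(ids = as.list(ids)),
                    n1 = if (is.null(categories)) list() else
                      list(categories = as.list(categories))),
       edges = list(e0 = list(subject = "n0", object = "n1",
                              predicates = as.list(predicates))))
}

test_that("config loading validates slots, URL-safety and duplicates", {
  dir <- withr::local_tempdir()
  writeLines('{"nodes_file": "n.tsv"}', file.path(dir, "bad.json"))
  expect_error(load_configs(dir), "edges_file", class = "onehop_config_error")
  expect_error(load_configs(withr::local_tempdir()), class = "onehop_config_error")

  dir2 <- withr::local_tempdir()
  base <- '{"nodes_file":"n.tsv","edges_file":"e.tsv","endpoint_name":"%s","semantic_model":"m.yaml"}'
  writeLines(sprintf(base, "kg2c"), file.path(dir2, "a.json"))
  writeLines(sprintf(base, "kg2c"), file.path(dir2, "b.json"))
  expect_error(load_configs(dir2), "duplicate", class = "onehop_config_error")

  dir3 <- withr::local_tempdir()
  writeLines(sprintf(base, "bad name!"), file.path(dir3, "a.json"))
  expect_error(load_configs(dir3), "URL-safe", class = "onehop_config_error")
})

test_that("the demo endpoint answers queries end to end", {
  st <- demo_state()
  expect_identical(st$endpoints$demo$status, "ok")
  r <- handle_request(st, "/demo/query", "POST", trapi_body(demo_query()))
  expect_identical(r$status, 200L)
  parsed <- jsonlite::fromJSON(r$body, simplifyVector = FALSE)
  expect_length(parsed$message$results, 2L)
  bound <- vapply(parsed$message$results,
                  function(res) res$node_bindings$n1[[1L]]$id, character(1))
  expect_setequal(bound, c("UniProtKB:P23219", "UniProtKB:P35354"))
})

test_that("multiplexed endpoints are served at separate sub-paths", {
  dir <- withr::local_tempdir()
  demo <- system.file("extdata", "demo", package = "onehop")
  model <- system.file("extdata", "mini_model.yaml", package = "onehop")
  for (ep in c("kg2c", "ctkp")) {
    jsonlite::write_json(list(
      nodes_file = file.path(demo, "nodes.tsv"),
      edges_file = file.path(demo, "edges.tsv"),
      endpoint_name = ep, semantic_model = model),
      file.path(dir, paste0(ep, ".json")), auto_unbox = TRUE)
  }
  st <- build_service(load_configs(dir))
  for (ep in c("kg2c", "ctkp")) {
    r <- handle_request(st, sprintf("/%s/query", ep), "POST",
                        trapi_body(demo_query()))
    expect_identical(r$status, 200L)
  }
  expect_identical(handle_request(st, "/nope/query", "POST",
                                  trapi_body(demo_query()))$status, 404L)
})

test_that("the full route table returns well-formed responses", {
  st <- demo_state()
  routes <- list(
    list("/demo/meta_knowledge_graph", "GET"),
    list("/demo/sri_test_triples", "GET"),
    list("/code_version", "GET"),
    list("/logs", "GET"),
    list("/healthcheck", "GET"))
  for (r in routes) {
    resp <- handle_request(st, r[[1L]], r[[2L]])
    expect_identical(resp$status, 200L, info = r[[1L]])
    expect_identical(resp$content_type, "application/json")
    expect_silent(jsonlite::fromJSON(resp$body, simplifyVector = FALSE))
  }
  mk <- jsonlite::fromJSON(handle_request(st, "/demo/meta_knowledge_graph")$body,
                           simplifyVector = FALSE)
  expect_true(all(c("nodes", "edges") %in% names(mk)))
  cv <- jsonlite::fromJSON(handle_request(st, "/code_version")$body,
                           simplifyVector = FALSE)
  expect_identical(cv$code_version,
                   as.character(utils::packageVersion("onehop")))
})

test_that("malformed queries produce 400s with explanations, not crashes", {
  st <- demo_state()
  r1 <- handle_request(st, "/demo/query", "POST", "{not json")
  expect_identical(r1$status, 400L)
  three <- list(
    nodes = list(n0 = list(ids = list("CHEBI:46195")), n1 = list(), n2 = list()),
    edges = list(e0 = list(subject = "n0", object = "n1"),
                 e1 = list(subject = "n1", object = "n2")))
  r2 <- handle_request(st, "/demo/query", "POST", trapi_body(three))
  expect_identical(r2$status, 400L)
  expect_match(jsonlite::fromJSON(r2$body)$validation_errors, "not one-hop",
               all = FALSE)
  r3 <- handle_request(st, "/demo/query", "POST",
                       trapi_body(demo_query(predicates = "biolink:frobnicates")))
  expect_identical(r3$status, 400L)
})

test_that("repeated identical requests return byte-identical bodies", {
  st <- demo_state()
  body <- trapi_body(demo_query())
  bodies <- vapply(seq_len(32L), function(i) {
    handle_request(st, "/demo/query", "POST", body)$body
  }, character(1))
  expect_length(unique(bodies), 1L)
})

test_that("snapshots let a second startup serve identically without re-parsing", {
  snap <- withr::local_tempdir()
  st1 <- demo_state(snapshot_dir = snap)
  expect_true(file.exists(file.path(snap, "demo", "manifest.json")))
  st2 <- demo_state(snapshot_dir = snap)
  expect_match(paste(onehop:::log_tail(st2$log), collapse = "\n"),
               "loaded snapshot")
  b1 <- handle_request(st1, "/demo/query", "POST", trapi_body(demo_query()))$body
  b2 <- handle_request(st2, "/demo/query", "POST", trapi_body(demo_query()))$body
  expect_identical(b1, b2)
})

test_that("a config with an unreachable source fails only that endpoint", {
  dir <- withr::local_tempdir()
  demo <- system.file("extdata", "demo", package = "onehop")
  model <- system.file("extdata", "mini_model.yaml", package = "onehop")
  jsonlite::write_json(list(
    nodes_file = file.path(demo, "nodes.tsv"),
    edges_file = file.path(dir, "missing_edges.tsv"),
    endpoint_name = "broken", semantic_model = model),
    file.path(dir, "broken.json"), auto_unbox = TRUE)
  jsonlite::write_json(list(
    nodes_file = file.path(demo, "nodes.tsv"),
    edges_file = file.path(demo, "edges.tsv"),
    endpoint_name = "fine", semantic_model = model),
    file.path(dir, "fine.json"), auto_unbox = TRUE)
  st <- build_service(load_configs(dir))
  expect_identical(st$endpoints$broken$status, "failed")
  expect_identical(st$endpoints$fine$status, "ok")
  expect_identical(handle_request(st, "/broken/query", "POST",
                                  trapi_body(demo_query()))$status, 503L)
  hc <- handle_request(st, "/healthcheck")
  expect_identical(hc$status, 503L)
  parsed <- jsonlite::fromJSON(hc$body)
  expect_identical(parsed$endpoints$broken, "failed")
})

test_that("rebuild requires the token and swaps state atomically", {
  dir <- withr::local_tempdir()
  model <- system.file("extdata", "mini_model.yaml", package = "onehop")
  # mutable KG files so the rebuild can observe new content
  writeLines(c("id\tname\tcategory",
               "X:1\talpha\tDrug", "X:2\tbeta\tProtein"),
             file.path(dir, "nodes.tsv"))
  writeLines(c("id\tsubject\tpredicate\tobject",
               "e1\tX:1\tphysically_interacts_with\tX:2"),
             file.path(dir, "edges.tsv"))
  token <- "s3cret"
  jsonlite::write_json(list(
    nodes_file = "nodes.tsv", edges_file = "edges.tsv",
    endpoint_name = "mut", semantic_model = model,
    rebuild_token_hash = digest::digest(token, algo = "sha256", serialize = FALSE)),
    file.path(dir, "mut.json"), auto_unbox = TRUE)
  st <- build_service(load_configs(dir))

  body <- trapi_body(demo_query(ids = "X:1", categories = NULL,
                                predicates = "biolink:interacts_with"))
  before <- jsonlite::fromJSON(handle_request(st, "/mut/query", "POST", body)$body,
                               simplifyVector = FALSE)
  expect_length(before$message$results, 1L)

  # grow the KG, then rebuild
  writeLines(c("id\tname\tcategory",
               "X:1\talpha\tDrug", "X:2\tbeta\tProtein", "X:3\tgamma\tProtein"),
             file.path(dir, "nodes.tsv"))
  writeLines(c("id\tsubject\tpredicate\tobject",
               "e1\tX:1\tphysically_interacts_with\tX:2",
               "e2\tX:1\tphysically_interacts_with\tX:3"),
             file.path(dir, "edges.tsv"))

  r_bad <- handle_request(st, "/rebuild", "POST",
                          headers = list(`x-rebuild-token` = "wrong"))
  expect_identical(r_bad$status, 401L)
  after_bad <- jsonlite::fromJSON(handle_request(st, "/mut/query", "POST", body)$body,
                                  simplifyVector = FALSE)
  expect_length(after_bad$message$results, 1L)   # no rebuild happened

  r_ok <- handle_request(st, "/rebuild", "POST",
                         headers = list(`x-rebuild-token` = token))
  expect_identical(r_ok$status, 202L)
  after <- jsonlite::fromJSON(handle_request(st, "/mut/query", "POST", body)$body,
                              simplifyVector = FALSE)
  expect_length(after$message$results, 2L)
})

test_that("rebuild is 404 when unconfigured", {
  st <- demo_state()
  r <- handle_request(st, "/rebuild", "POST",
                      headers = list(`x-rebuild-token` = "whatever"))
  expect_identical(r$status, 404L)
})
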