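test_that("the request handler grounds the worked example", {
  idx <- build_index(pkc_fixture())
  res <- handle_request("POST", "/ground",
                        '{"text": "PKC-Delta"}', idx)
  expect_equal(res$status, 200L)
  parsed <- jsonlite::fromJSON(res$body, simplifyVector = FALSE)
  expect_length(parsed, 1L)
  expect_equal(parsed[[1]]$term$namespace, "HGNC")
  expect_equal(parsed[[1]]$term$id, "9399")
  expect_equal(round(parsed[[1]]$score, 4), 0.9936)
})

test_that("the request handler rejects bad input with error payloads", {
  idx <- build_index(pkc_fixture())
  res <- handle_request("POST", "/ground", "{}", idx)
  expect_equal(res$status, 400L)
  expect_match(jsonlite::fromJSON(res$body)$error, "text")
  res <- handle_request("POST", "/ground", "not json", idx)
  expect_equal(res$status, 400L)
  res <- handle_request("GET", "/nope", "", idx)
  expect_equal(res$status, 404L)
  big <- paste(rep("x", 2048), collapse = "")
  res <- handle_request("POST", "/ground", big, idx, max_body = 1024)
  expect_equal(res$status, 413L)
  expect_match(jsonlite::fromJSON(res$body)$error, "1024")
})

test_that("the models endpoint lists deployed disambiguation strings", {
  idx <- build_index(dap4_fixture())
  corp <- generate_ambiguous_corpus("DAP4", docs_per_sense = 20, seed = 3)
  reg <- model_registry(list(train_disambiguator(corp, seed = 3)))
  res <- handle_request("GET", "/models", "", idx, models = reg)
  expect_equal(res$status, 200L)
  expect_equal(jsonlite::fromJSON(res$body), "dap4")
  res0 <- handle_request("GET", "/models", "", idx)
  expect_equal(jsonlite::fromJSON(res0$body), list())
})

test_that("organism priorities reorder tied orthologs through the handler", {
  terms <- dplyr::bind_rows(
    term_table("SYNT", "H1", "GENE1", "standard_name", "GENE1", "synth",
               organism = "9606"),
    term_table("SYNT", "M1", "GENE1", "standard_name", "Gene1m", "synth",
               organism = "10090"))
  idx <- build_index(terms)
  res <- handle_request("POST", "/ground",
                        '{"text": "GENE1", "organisms": ["10090", "9606"]}',
                        idx)
  parsed <- jsonlite::fromJSON(res$body, simplifyVector = FALSE)
  expect_equal(parsed[[1]]$term$organism, "10090")
  expect_equal(parsed[[2]]$term$organism, "9606")
})

test_that("CLI and REST produce byte-identical JSON for identical input", {
  terms_path <- withr::local_tempfile(fileext = ".tsv")
  write_terms(pkc_fixture(), terms_path)
  idx <- build_index(pkc_fixture())
  for (q in c("PKC-Delta", "MAP2K1")) {
    cli_out <- run_cli(c("ground", "--terms", terms_path, "--text", q))
    rest_out <- handle_request("POST", "/ground",
                               jsonlite::toJSON(list(text = q),
                                                auto_unbox = TRUE), idx)$body
    expect_identical(cli_out, rest_out)
  }
})

test_that("the live socket service answers a ground request", {
  skip_if_not_installed("callr")
  terms <- pkc_fixture()
  port <- 18000L + (Sys.getpid() %% 2000L)
  server <- callr::r_bg(function(terms, port) {
    idx <- grounder::build_index(terms)
    grounder::serve(idx, port = port, max_requests = 1)
  }, args = list(terms = terms, port = port), libpath = .libPaths())
  on.exit(server$kill(), add = TRUE)
  body <- '{"text": "PKC-Delta"}'
  response <- NULL
  for (i in 1:50) {
    Sys.sleep(0.2)
    response <- tryCatch({
      con <- socketConnection("127.0.0.1", port, blocking = TRUE,
                              open = "r+b", timeout = 10)
      writeBin(charToRaw(paste0(
        "POST /ground HTTP/1.1\r\nHost: localhost\r\n",
        "Content-Length: ", nchar(body), "\r\n\r\n", body)), con)
      raw <- rawToChar(readBin(con, "raw", n = 65536))
      close(con)
      raw
    }, error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(response) && nzchar(response)) break
  }
  expect_false(is.null(response))
  expect_match(response, "HTTP/1.1 200 OK", fixed = TRUE)
  payload <- sub(".*\r\n\r\n", "", response)
  expect_identical(payload, ground_json(build_index(terms), "PKC-Delta"))
})
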