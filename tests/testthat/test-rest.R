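test_that("the route manifest covers every entity and declared plugin", {
  m <- example_model()
  routes <- rest_routes(m)
  for (e in entity_names(m)) {
    sub <- routes[!is.na(routes$entity) & routes$entity == e, ]
    expect_setequal(sub$action, c("find", "get", "add", "update", "remove"))
    expect_true(all(grepl(paste0("^/api/v1/", tolower(e)), sub$path)))
  }
  plugin <- routes[grepl("^plugin:", routes$action), ]
  expect_identical(plugin$path, "/api/v1/_plugin/app.header")
})

test_that("collection GET maps query params to filters and pages", {
  s <- example_store()
  on.exit(store_close(s))
  app <- rest_app(s)
  res <- handle_request(app, "GET", "/api/v1/sample",
                        query = list(Experiment = "E1"))
  expect_identical(res$status, 200L)
  body <- jsonlite::fromJSON(res$body, simplifyVector = FALSE)
  expect_length(body$items, 1)
  expect_identical(body$items[[1]]$ID, "S1")
  expect_identical(body$total, 1L)

  paged <- jsonlite::fromJSON(
    handle_request(app, "GET", "/api/v1/experiment",
                   query = list(`_limit` = "1", `_offset` = "1",
                                `_sort` = "ID"))$body,
    simplifyVector = FALSE)
  expect_identical(paged$total, 2L)
  expect_length(paged$items, 1)
  expect_identical(paged$items[[1]]$ID, "E2")
  expect_identical(paged$offset, 1L)
})

test_that("POST then GET round-trips a record; errors map to 4xx codes", {
  s <- example_store()
  on.exit(store_close(s))
  app <- rest_app(s)
  rec <- list(ID = "E9", Title = "new", Medium = "m", Stress = "s")
  post <- handle_request(app, "POST", "/api/v1/experiment",
                         body = jsonlite::toJSON(rec, auto_unbox = TRUE))
  expect_identical(post$status, 201L)
  got <- handle_request(app, "GET", "/api/v1/experiment/E9")
  expect_identical(got$status, 200L)
  parsed <- jsonlite::fromJSON(got$body, simplifyVector = FALSE)
  expect_identical(parsed[c("ID", "Title", "Medium", "Stress")], rec)

  nf <- handle_request(app, "GET", "/api/v1/banana")
  expect_identical(nf$status, 404L)
  expect_identical(jsonlite::fromJSON(nf$body)$code, "ENTITY_UNKNOWN")

  dup <- handle_request(app, "POST", "/api/v1/experiment",
                        body = jsonlite::toJSON(rec, auto_unbox = TRUE))
  expect_identical(dup$status, 409L)
  expect_identical(jsonlite::fromJSON(dup$body)$code, "DUPLICATE_KEY")

  blocked <- handle_request(app, "DELETE", "/api/v1/experiment/E1")
  expect_identical(blocked$status, 409L)
  expect_identical(jsonlite::fromJSON(blocked$body)$code, "REFERENTIAL_BLOCK")

  bad <- handle_request(app, "PUT", "/api/v1/experiment/E9",
                        body = "{not json")
  expect_identical(bad$status, 400L)
})

test_that("API mutations are observable via the data layer and vice versa", {
  s <- example_store()
  on.exit(store_close(s))
  app <- rest_app(s)
  # API -> data layer
  handle_request(app, "PUT", "/api/v1/experiment/E2",
                 body = jsonlite::toJSON(list(Title = "renamed"),
                                         auto_unbox = TRUE))
  expect_identical(ga_get(s, "Experiment", "E2")$Title, "renamed")
  handle_request(app, "DELETE", "/api/v1/experiment/E2")
  expect_ga_error(ga_get(s, "Experiment", "E2"), "NOT_FOUND")
  # data layer -> API
  ga_add(s, "Experiment", list(ID = "E3", Title = "direct", Medium = "m",
                               Stress = "s"))
  got <- handle_request(app, "GET", "/api/v1/experiment/E3")
  expect_identical(jsonlite::fromJSON(got$body)$Title, "direct")
})

test_that("plugin extension points mount and answer through the service", {
  s <- example_store()
  on.exit(store_close(s))
  app <- rest_app(s)
  unreg <- handle_request(app, "GET", "/api/v1/_plugin/app.header")
  expect_identical(unreg$status, 501L)
  register_plugin(app, "app.header", function(method, query, body) {
    list(status = 200L, body = list(banner = "hello"))
  })
  ok <- handle_request(app, "GET", "/api/v1/_plugin/app.header")
  expect_identical(ok$status, 200L)
  expect_identical(jsonlite::fromJSON(ok$body)$banner, "hello")
  expect_ga_error(register_plugin(app, "no.such.plugin", identity),
                  "PLUGIN_UNKNOWN")
})

test_that("the HTTP adapter serves the same responses over a live socket", {
  db <- tempfile(fileext = ".db")
  store <- store_open(example_model(), db)
  ga_add(store, "Experiment",
         list(ID = "E1", Title = "t", Medium = "glucose", Stress = "42C"))
  store_close(store)
  port <- 18000L + (Sys.getpid() %% 2000L)
  script <- sprintf(
    "library(genapp); m <- load_model('%s'); s <- store_open(m, '%s'); serve(rest_app(s), port = %d)",
    example_model_path(), db, port)
  proc <- system2("Rscript", c("-e", shQuote(script)), wait = FALSE,
                  stdout = FALSE, stderr = FALSE)
  on.exit(system(sprintf(
    "pkill -f 'port = %d' >/dev/null 2>&1 || true", port)), add = TRUE)
  url <- sprintf("http://127.0.0.1:%d/api/v1/experiment/E1", port)
  body <- NULL
  for (i in 1:50) {
    Sys.sleep(0.2)
    res <- tryCatch(curl::curl_fetch_memory(url), error = function(e) NULL)
    if (!is.null(res)) { body <- rawToChar(res$content); break }
  }
  expect_false(is.null(body), label = "live server answered within 10 s")
  if (!is.null(body))
    expect_identical(jsonlite::fromJSON(body)$Medium, "glucose")
})
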