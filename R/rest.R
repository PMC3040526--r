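#' @title REST/JSON service
#'
#' @description
#' Every generated application exposes the same programmatic interface:
#' per entity `GET /api/v1/{entity}` (query parameters become equality
#' filters; `_offset`, `_limit`, `_sort` control paging and order),
#' `GET /api/v1/{entity}/{key}`, `POST` to add, `PUT /{key}` to update and
#' `DELETE /{key}` to remove. Collections come wrapped in
#' `{"items":[...],"total":n,"offset":o,"limit":l}`; errors map to 4xx
#' with `{"code","message"}`. Entity names are lowercased in paths; JSON
#' field names are the model field names verbatim.
#'
#' Each declared ui *plugin* additionally yields a named extension point
#' mounted at `/api/v1/_plugin/{plugin_id}` where an operator can register
#' a handler via [register_plugin()]; unregistered points answer 501.
#'
#' @name rest-service
NULL

#' Route manifest for a model
#'
#' @param model a valid, resolved [ga_model()]
#' @return data frame with columns `method`, `path`, `entity`, `action`
#' @export
rest_routes <- function(model) {
  assert_valid(model)
  rows <- list()
  for (e in model$entities) {
    p <- paste0("/api/v1/", tolower(e$name))
    rows[[length(rows) + 1L]] <- data.frame(
      method = c("GET", "GET", "POST", "PUT", "DELETE"),
      path = c(p, paste0(p, "/{key}"), p, paste0(p, "/{key}"),
               paste0(p, "/{key}")),
      entity = e$name,
      action = c("find", "get", "add", "update", "remove"),
      stringsAsFactors = FALSE)
  }
  for (pl in collect_plugins(model$ui)) {
    rows[[length(rows) + 1L]] <- data.frame(
      method = "ANY", path = paste0("/api/v1/_plugin/", pl$plugin_id),
      entity = NA_character_, action = paste0("plugin:", pl$name),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(method = character(), path = character(),
                      entity = character(), action = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

collect_plugins <- function(ui) {
  out <- list()
  for (el in ui) {
    if (identical(el$kind, "plugin")) out[[length(out) + 1L]] <- el
    out <- c(out, collect_plugins(el$children))
  }
  out
}

#' Build an application object around a store
#'
#' @param store a [store_open()] handle
#' @return a `ga_app` that [handle_request()] and [serve()] operate on
#' @export
rest_app <- function(store) {
  structure(list(store = store, routes = rest_routes(store$model),
                 plugins = new.env(parent = emptyenv())),
            class = "ga_app")
}

#' Register a handler on a plugin extension point
#'
#' @param app a [rest_app()]
#' @param plugin_id extension-point identifier declared in the model's ui
#' @param handler `function(method, query, body) -> list(status, body)`
#' @return the app, invisibly
#' @export
register_plugin <- function(app, plugin_id, handler) {
  ids <- vapply(collect_plugins(app$store$model$ui), `[[`, "", "plugin_id")
  if (!plugin_id %in% ids)
    ga_stop("PLUGIN_UNKNOWN",
            sprintf("model declares no plugin with id '%s'", plugin_id))
  assign(plugin_id, handler, envir = app$plugins)
  invisible(app)
}

json_out <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, na = "null", null = "null",
                   dataframe = "rows", digits = NA)
}

http_error_status <- function(code) {
  switch(code,
    ENTITY_UNKNOWN = 404L, NOT_FOUND = 404L, QUERY_UNKNOWN_FIELD = 400L,
    QUERY_BAD_OP = 400L, QUERY_BAD_PAGE = 400L, NOT_NILLABLE = 422L,
    XREF_UNRESOLVED = 422L, DUPLICATE_KEY = 409L,
    READONLY_VIOLATION = 409L, REFERENTIAL_BLOCK = 409L,
    VALUE_BAD_TYPE = 422L, BAD_REQUEST = 400L, 400L)
}

#' Handle one API request
#'
#' The pure core of the service: [serve()] is a thin HTTP adapter over
#' this function, and tests drive it directly.
#'
#' @param app a [rest_app()]
#' @param method HTTP verb
#' @param path request path, e.g. `"/api/v1/sample"`
#' @param query named list/character of query parameters
#' @param body request body text (JSON object) for POST/PUT
#' @return `list(status = int, body = json text)`
#' @export
handle_request <- function(app, method, path, query = list(), body = NULL) {
  res <- tryCatch(
    dispatch_request(app, toupper(method), path, query, body),
    genapp_error = function(cond) {
      code <- error_code(cond)
      list(status = http_error_status(code),
           body = json_out(list(code = code,
                                message = conditionMessage(cond))))
    })
  res
}

dispatch_request <- function(app, method, path, query, body) {
  store <- app$store
  parts <- strsplit(sub("^/", "", path), "/", fixed = TRUE)[[1]]
  if (length(parts) < 3 || parts[1] != "api" || parts[2] != "v1")
    ga_stop("NOT_FOUND", sprintf("no route for '%s'", path))
  if (identical(parts[3], "_plugin")) {
    if (length(parts) < 4) ga_stop("NOT_FOUND", "missing plugin id")
    id <- utils::URLdecode(parts[4])
    handler <- if (exists(id, envir = app$plugins))
      get(id, envir = app$plugins)
    if (is.null(handler))
      return(list(status = 501L,
                  body = json_out(list(code = "PLUGIN_NOT_REGISTERED",
                                       message = sprintf(
                                         "no handler registered for '%s'", id)))))
    out <- handler(method, query, body)
    return(list(status = out$status %||% 200L, body = json_out(out$body)))
  }
  e <- find_entity(store$model, parts[3])
  if (is.null(e))
    ga_stop("ENTITY_UNKNOWN", sprintf("unknown entity '%s'", parts[3]))
  key <- if (length(parts) >= 4) utils::URLdecode(parts[4])

  if (identical(method, "GET") && is.null(key)) {
    q <- as.list(query)
    offset <- as.integer(q[["_offset"]] %||% 0L)
    limit <- as.integer(q[["_limit"]] %||% 100L)
    sort <- q[["_sort"]]
    q[c("_offset", "_limit", "_sort")] <- NULL
    filters <- lapply(names(q), function(nm) flt(nm, "equals", q[[nm]]))
    res <- ga_find(store, e, filters = filters, page = pg(offset, limit),
                   sort = sort)
    return(list(status = 200L,
                body = json_out(list(items = record_list(res$records),
                                     total = res$total, offset = offset,
                                     limit = limit))))
  }
  if (identical(method, "GET")) {
    rec <- ga_get(store, e, key)
    return(list(status = 200L, body = json_out(record_list(rec)[[1]])))
  }
  if (identical(method, "POST") && is.null(key)) {
    rec <- parse_body(body)
    stored <- ga_add(store, e, rec)
    return(list(status = 201L, body = json_out(record_list(stored)[[1]])))
  }
  if (identical(method, "PUT") && !is.null(key)) {
    rec <- parse_body(body)
    stored <- ga_update(store, e, key, rec)
    return(list(status = 200L, body = json_out(record_list(stored)[[1]])))
  }
  if (identical(method, "DELETE") && !is.null(key)) {
    n <- ga_remove(store, e, key)
    return(list(status = 200L, body = json_out(list(removed = n))))
  }
  ga_stop("NOT_FOUND", sprintf("no route for %s %s", method, path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_body <- function(body) {
  if (is.null(body) || !nzchar(body))
    ga_stop("BAD_REQUEST", "request body must be a JSON object")
  rec <- tryCatch(jsonlite::fromJSON(body, simplifyVector = TRUE),
                  error = function(e)
                    ga_stop("BAD_REQUEST",
                            paste("invalid JSON body:", conditionMessage(e))))
  if (!is.list(rec)) ga_stop("BAD_REQUEST", "JSON body must be an object")
  rec
}

# data frame -> list of per-row named lists (JSON objects)
record_list <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    row <- lapply(df[i, , drop = FALSE], function(col) {
      v <- col[[1]]
      if (inherits(v, "Date")) v <- format(v, "%Y-%m-%d")
      if (length(v) == 1 && is.na(v)) NULL else v
    })
    row
  })
}

#' Serve a model's REST API over HTTP
#'
#' Thin blocking adapter mounting [handle_request()] on an HTTP port via
#' the httpuv event loop. Intended for the command-line entry point;
#' programmatic use and tests go through [handle_request()] directly.
#'
#' @param app a [rest_app()]
#' @param port TCP port
#' @param host interface to bind (default loopback)
#' @return does not return until interrupted
#' @export
serve <- function(app, port = 8080L, host = "127.0.0.1") {
  if (!requireNamespace("httpuv", quietly = TRUE))
    ga_stop("SERVE_UNAVAILABLE", "serving requires the 'httpuv' package")
  handler <- function(req) {
    query <- parse_query_string(req$QUERY_STRING %||% "")
    body <- tryCatch(rawToChar(req$rook.input$read()),
                     error = function(e) NULL)
    res <- handle_request(app, req$REQUEST_METHOD, req$PATH_INFO,
                          query = query, body = body)
    message(sprintf("%s %s -> %d", req$REQUEST_METHOD, req$PATH_INFO,
                    res$status))
    list(status = res$status,
         headers = list("Content-Type" = "application/json"),
         body = res$body)
  }
  srv <- httpuv::startServer(host, port, list(call = handler))
  on.exit(httpuv::stopServer(srv), add = TRUE)
  message(sprintf("serving on http://%s:%d/api/v1/ (Ctrl-C to stop)",
                  host, port))
  httpuv::service(Inf)
}

parse_query_string <- function(qs) {
  if (!nzchar(qs)) return(list())
  qs <- sub("^\\?", "", qs)
  pairs <- strsplit(strsplit(qs, "&", fixed = TRUE)[[1]], "=", fixed = TRUE)
  out <- list()
  for (p in pairs) {
    if (length(p) == 0 || !nzchar(p[1])) next
    out[[utils::URLdecode(p[1])]] <-
      utils::URLdecode(if (length(p) > 1) p[2] else "")
  }
  out
}
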