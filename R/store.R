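#' Open a data store for a model
#'
#' Creates (or reopens) the SQLite database backing a generated
#' application and executes the model's [schema_ddl()] when the tables do
#' not exist yet. Foreign-key enforcement is switched on for the
#' connection.
#'
#' @param model a valid, resolved [ga_model()]
#' @param path database file path, or `":memory:"` (default) for an
#'   in-memory store
#' @return a `ga_store` handle
#' @export
store_open <- function(model, path = ":memory:") {
  assert_valid(model)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
  existing <- tolower(DBI::dbListTables(con))
  for (stmt in sql_statements(schema_ddl(model))) {
    tbl <- sub("(?s)^CREATE TABLE (\\w+).*", "\\1", stmt, perl = TRUE)
    if (!tolower(tbl) %in% existing) DBI::dbExecute(con, stmt)
  }
  structure(list(con = con, model = model), class = "ga_store")
}

#' Close a store
#' @param store a `ga_store`
#' @return invisibly, `TRUE`
#' @export
store_close <- function(store) {
  DBI::dbDisconnect(store$con)
  invisible(TRUE)
}

#' @export
print.ga_store <- function(x, ...) {
  cat(sprintf("<ga_store> model '%s', %d entities\n",
              x$model$name, length(x$model$entities)))
  invisible(x)
}

# dbGetQuery refuses an empty params list; route all queries through here
dbq <- function(con, sql, params = list()) {
  if (length(params) == 0) DBI::dbGetQuery(con, sql)
  else DBI::dbGetQuery(con, sql, params = params)
}

# split a DDL script into single statements (no ';' occurs inside our DDL)
sql_statements <- function(script) {
  stmts <- strsplit(script, ";")[[1]]
  stmts <- trimws(stmts)
  stmts[nzchar(stmts)]
}

store_entity <- function(store, entity) {
  if (inherits(entity, "ga_entity")) return(entity)
  e <- find_entity(store$model, entity)
  if (is.null(e))
    ga_stop("ENTITY_UNKNOWN", sprintf("unknown entity '%s'", entity))
  e
}

# --- value encoding between R and SQLite --------------------------------

# resolve the effective scalar type of a field (through one xref hop)
effective_type <- function(field, model) {
  if (!identical(field$type, "xref")) return(field$type)
  tf <- find_field(find_entity(model, field$xref_entity), field$xref_field)
  tf$type
}

# R value -> DB storage value (bool as 0/1, date as ISO text)
encode_value <- function(value, field, model) {
  if (is.null(value) || (length(value) == 1 && is.na(value))) return(NA)
  type <- effective_type(field, model)
  switch(type,
    int = as.integer(value),
    decimal = as.numeric(value),
    bool = as.integer(as.logical(value)),
    date = format(as.Date(value), "%Y-%m-%d"),
    as.character(value))
}

# DB column -> R typed vector
decode_column <- function(x, field, model) {
  type <- effective_type(field, model)
  switch(type,
    int = as.integer(x),
    decimal = as.numeric(x),
    bool = as.logical(x),
    date = as.Date(as.character(x)),
    as.character(x))
}

# parse a text cell (from a TSV file or URL) into an R value; "" = NULL
parse_cell <- function(text, field, model) {
  if (is.na(text) || identical(text, "")) return(NA)
  type <- effective_type(field, model)
  out <- switch(type,
    int = suppressWarnings(as.integer(text)),
    decimal = suppressWarnings(as.numeric(text)),
    bool = if (tolower(text) %in% c("true", "false"))
      tolower(text) == "true" else NA,
    date = tryCatch(as.Date(text, format = "%Y-%m-%d"),
                    error = function(e) as.Date(NA)),
    text)
  if (length(out) != 1 || is.na(out))
    ga_stop("VALUE_BAD_TYPE",
            sprintf("'%s' is not a valid %s for field '%s'",
                    text, type, field$name))
  out
}

# R value -> canonical text cell for export ("" encodes NULL)
format_cell <- function(value, field, model) {
  if (length(value) == 0 || is.na(value)) return("")
  type <- effective_type(field, model)
  switch(type,
    bool = if (as.logical(value)) "true" else "false",
    date = format(as.Date(value), "%Y-%m-%d"),
    decimal = format(as.numeric(value), scientific = FALSE, trim = TRUE),
    as.character(value))
}
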