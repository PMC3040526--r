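#' @title CRUD operations
#'
#' @description
#' The runtime data layer every generated application shares: add, update,
#' remove, find and count records of any modeled entity, with conjunctive
#' filters, deterministic sorting and offset/limit pagination. All
#' structural rules of the model (required values, uniqueness, resolvable
#' cross-references, read-only fields) are enforced here with typed errors.
#'
#' @name crud
NULL

GA_FILTER_OPS <- c(equals = "=", like = "LIKE", lt = "<", le = "<=",
                   gt = ">", ge = ">=")
GA_MAX_LIMIT <- 1000L

#' Build a filter
#' @param field field name on the queried entity
#' @param op one of `equals, like, lt, le, gt, ge` (`like` patterns use
#'   `%`/`_` wildcards and apply to string/text fields only)
#' @param value literal to compare with
#' @return a `ga_filter`
#' @export
flt <- function(field, op = "equals", value) {
  if (!op %in% names(GA_FILTER_OPS))
    ga_stop("QUERY_BAD_OP", sprintf("unknown filter op '%s'", op))
  structure(list(field = field, op = op, value = value), class = "ga_filter")
}

#' Build a page
#' @param offset rows to skip (0-based)
#' @param limit maximum rows to return (capped at 1000)
#' @return a `ga_page`
#' @export
pg <- function(offset = 0L, limit = 100L) {
  offset <- as.integer(offset); limit <- as.integer(limit)
  if (is.na(offset) || offset < 0L) ga_stop("QUERY_BAD_PAGE", "offset must be >= 0")
  if (is.na(limit) || limit < 1L || limit > GA_MAX_LIMIT)
    ga_stop("QUERY_BAD_PAGE",
            sprintf("limit must be in 1..%d", GA_MAX_LIMIT))
  structure(list(offset = offset, limit = limit), class = "ga_page")
}

#' Navigation helpers over a paged result
#'
#' First/previous/next/last record navigation is plain offset arithmetic
#' on the server-side total; no session state is kept.
#'
#' @param total total matching records
#' @param offset current offset
#' @return the offset of the first, previous, next and last record
#' @export
page_nav <- function(total, offset) {
  total <- as.integer(total); offset <- as.integer(offset)
  list(first = 0L,
       previous = max(0L, offset - 1L),
       `next` = min(max(total - 1L, 0L), offset + 1L),
       last = max(total - 1L, 0L))
}

check_record_fields <- function(entity, record) {
  unknown <- setdiff(tolower(names(record)), tolower(field_names(entity)))
  if (length(unknown) > 0)
    ga_stop("QUERY_UNKNOWN_FIELD",
            sprintf("no field(s) %s on entity '%s'",
                    paste0("'", unknown, "'", collapse = ", "), entity$name))
}

record_value <- function(record, fname) {
  idx <- match(tolower(fname), tolower(names(record)))
  if (is.na(idx)) NULL else record[[idx]]
}

# verify an xref value points at an existing target row
check_xref_resolves <- function(store, field, value) {
  if (is.null(value) || is.na(value)) return(invisible(TRUE))
  target <- find_entity(store$model, field$xref_entity)
  sql <- sprintf("SELECT COUNT(*) AS n FROM %s WHERE %s = ?",
                 target$name, find_field(target, field$xref_field)$name)
  n <- DBI::dbGetQuery(store$con, sql,
                       params = list(encode_value(value, field, store$model)))$n
  if (n == 0)
    ga_stop("XREF_UNRESOLVED",
            sprintf("no %s with %s = '%s'", field$xref_entity,
                    field$xref_field, value))
  invisible(TRUE)
}

#' Add a record
#'
#' @param store a [store_open()] handle
#' @param entity entity name or `ga_entity`
#' @param record named list of field values (R types or text); absent
#'   nillable fields become NULL, absent fields with a model default take
#'   that default
#' @return the stored record as a one-row data frame
#' @export
ga_add <- function(store, entity, record) {
  e <- store_entity(store, entity)
  check_record_fields(e, record)
  values <- list()
  for (f in e$fields) {
    v <- record_value(record, f$name)
    if (is.null(v) && !is.na(f$default_value))
      v <- parse_cell(f$default_value, f, store$model)
    if (is.character(v) && !identical(f$type, "string") &&
        !identical(f$type, "text"))
      v <- parse_cell(v, f, store$model)
    if ((is.null(v) || (length(v) == 1 && is.na(v))) && !isTRUE(f$nillable))
      ga_stop("NOT_NILLABLE",
              sprintf("field '%s' of '%s' requires a value", f$name, e$name))
    if (identical(f$type, "xref")) check_xref_resolves(store, f, v)
    values[[f$name]] <- encode_value(v, f, store$model)
  }
  sql <- sprintf("INSERT INTO %s (%s) VALUES (%s)", e$name,
                 paste(names(values), collapse = ", "),
                 paste(rep("?", length(values)), collapse = ", "))
  tryCatch(
    DBI::dbExecute(store$con, sql, params = unname(values)),
    error = function(err) {
      msg <- conditionMessage(err)
      code <- if (grepl("UNIQUE", msg)) "DUPLICATE_KEY"
              else if (grepl("NOT NULL", msg)) "NOT_NILLABLE"
              else if (grepl("FOREIGN KEY", msg, ignore.case = TRUE)) "XREF_UNRESOLVED"
              else "STORE_ERROR"
      ga_stop(code, msg)
    })
  key <- key_field(e)
  ga_get(store, e, decode_scalar(values[[key$name]], key, store$model))
}

decode_scalar <- function(v, field, model) decode_column(v, field, model)[1]

#' Fetch one record by key
#' @inheritParams ga_add
#' @param key value of the entity's key (its first unique field)
#' @return one-row data frame
#' @export
ga_get <- function(store, entity, key) {
  e <- store_entity(store, entity)
  kf <- key_field(e)
  res <- ga_find(store, e, filters = list(flt(kf$name, "equals", key)))
  if (res$total == 0)
    ga_stop("NOT_FOUND", sprintf("no %s with %s = '%s'", e$name, kf$name, key))
  res$records
}

#' Find records
#'
#' @inheritParams ga_add
#' @param filters list of [flt()] combined conjunctively
#' @param page a [pg()] window, or `NULL` for all rows
#' @param sort field name to order by (the entity key is always appended as
#'   the final tie-break, making the order deterministic)
#' @return `list(records = data.frame, total = n)` where `total` ignores
#'   the page window
#' @export
ga_find <- function(store, entity, filters = list(), page = NULL,
                    sort = NULL) {
  e <- store_entity(store, entity)
  where <- build_where(store, e, filters)
  kf <- key_field(e)
  sort_field <- if (!is.null(sort)) {
    sf <- find_field(e, sort)
    if (is.null(sf))
      ga_stop("QUERY_UNKNOWN_FIELD",
              sprintf("no field '%s' on entity '%s'", sort, e$name))
    sf$name
  }
  order_by <- paste(unique(c(sort_field, kf$name)), collapse = ", ")
  total <- dbq(store$con,
               paste0("SELECT COUNT(*) AS n FROM ", e$name, where$clause),
               where$params)$n
  sql <- paste0("SELECT ", paste(field_names(e), collapse = ", "),
                " FROM ", e$name, where$clause, " ORDER BY ", order_by)
  params <- where$params
  if (!is.null(page)) {
    sql <- paste0(sql, " LIMIT ? OFFSET ?")
    params <- c(params, list(page$limit, page$offset))
  }
  raw <- dbq(store$con, sql, params)
  records <- as.data.frame(
    lapply(stats::setNames(field_names(e), field_names(e)), function(fn) {
      decode_column(raw[[fn]], find_field(e, fn), store$model)
    }), stringsAsFactors = FALSE, optional = TRUE)
  if (nrow(raw) == 0) records <- records[0, , drop = FALSE]
  list(records = records, total = as.integer(total))
}

build_where <- function(store, e, filters) {
  if (length(filters) == 0) return(list(clause = "", params = list()))
  clauses <- character(); params <- list()
  for (f in filters) {
    fd <- find_field(e, f$field)
    if (is.null(fd))
      ga_stop("QUERY_UNKNOWN_FIELD",
              sprintf("no field '%s' on entity '%s'", f$field, e$name))
    if (identical(f$op, "like") &&
        !effective_type(fd, store$model) %in% c("string", "text"))
      ga_stop("QUERY_BAD_OP",
              sprintf("'like' applies to string/text fields only; '%s' is %s",
                      fd$name, effective_type(fd, store$model)))
    v <- f$value
    if (is.character(v) && !identical(f$op, "like"))
      v <- parse_cell(v, fd, store$model)
    clauses <- c(clauses, sprintf("%s %s ?", fd$name, GA_FILTER_OPS[[f$op]]))
    params <- c(params,
                list(if (identical(f$op, "like")) as.character(f$value)
                     else encode_value(v, fd, store$model)))
  }
  list(clause = paste0(" WHERE ", paste(clauses, collapse = " AND ")),
       params = params)
}

#' Count records
#' @inheritParams ga_find
#' @return integer count
#' @export
ga_count <- function(store, entity, filters = list()) {
  ga_find(store, entity, filters = filters)$total
}

#' Update a record
#'
#' Rejects changes to read-only fields (`READONLY_VIOLATION`): a read-only
#' field is fixed at creation time.
#'
#' @inheritParams ga_get
#' @param changes named list of new field values
#' @return the stored record after the update
#' @export
ga_update <- function(store, entity, key, changes) {
  e <- store_entity(store, entity)
  check_record_fields(e, changes)
  current <- ga_get(store, e, key)   # NOT_FOUND when absent
  kf <- key_field(e)
  sets <- character(); params <- list()
  for (nm in names(changes)) {
    f <- find_field(e, nm)
    v <- changes[[nm]]
    if (is.character(v) && !identical(f$type, "string") &&
        !identical(f$type, "text") && !is.na(v) && nzchar(v))
      v <- parse_cell(v, f, store$model)
    if (isTRUE(f$readonly)) {
      old <- current[[f$name]][1]
      same <- (is.na(old) && (is.null(v) || is.na(v))) ||
        (!is.na(old) && !is.null(v) && !is.na(v) && old == v)
      if (!same)
        ga_stop("READONLY_VIOLATION",
                sprintf("field '%s' of '%s' is read only", f$name, e$name))
      next
    }
    if ((is.null(v) || (length(v) == 1 && is.na(v))) && !isTRUE(f$nillable))
      ga_stop("NOT_NILLABLE",
              sprintf("field '%s' of '%s' requires a value", f$name, e$name))
    if (identical(f$type, "xref")) check_xref_resolves(store, f, v)
    sets <- c(sets, paste0(f$name, " = ?"))
    params <- c(params, list(encode_value(v, f, store$model)))
  }
  if (length(sets) > 0) {
    sql <- sprintf("UPDATE %s SET %s WHERE %s = ?", e$name,
                   paste(sets, collapse = ", "), kf$name)
    params <- c(params, list(encode_value(key, kf, store$model)))
    tryCatch(DBI::dbExecute(store$con, sql, params = params),
             error = function(err) {
               msg <- conditionMessage(err)
               code <- if (grepl("UNIQUE", msg)) "DUPLICATE_KEY" else "STORE_ERROR"
               ga_stop(code, msg)
             })
  }
  new_key <- record_value(changes, kf$name)
  ga_get(store, e, if (is.null(new_key) || isTRUE(key_field(e)$readonly)) key
                   else new_key)
}

#' Remove a record
#'
#' Removal is blocked (`REFERENTIAL_BLOCK`) while other rows still
#' reference the record, protecting referential integrity.
#'
#' @inheritParams ga_get
#' @return number of rows removed (1)
#' @export
ga_remove <- function(store, entity, key) {
  e <- store_entity(store, entity)
  kf <- key_field(e)
  row <- ga_get(store, e, key)  # NOT_FOUND when absent
  # inbound references from any entity (including self) block removal,
  # whichever unique field of this entity they target
  for (src in store$model$entities) {
    for (f in xref_fields(src)) {
      if (tolower(f$xref_entity) != tolower(e$name)) next
      tf <- find_field(e, f$xref_field)
      refval <- row[[tf$name]][1]
      if (is.na(refval)) next
      n <- DBI::dbGetQuery(
        store$con,
        sprintf("SELECT COUNT(*) AS n FROM %s WHERE %s = ?",
                src$name, f$name),
        params = list(encode_value(refval, tf, store$model)))$n
      if (n > 0)
        ga_stop("REFERENTIAL_BLOCK",
                sprintf("%d %s row(s) still reference %s '%s'",
                        n, src$name, e$name, key))
    }
  }
  DBI::dbExecute(store$con,
                 sprintf("DELETE FROM %s WHERE %s = ?", e$name, kf$name),
                 params = list(encode_value(key, kf, store$model)))
}
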