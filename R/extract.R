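#' @title Reverse engineering a model from a relational schema
#'
#' @description
#' Legacy databases gain generated interfaces by extracting a model from
#' their schema: tables become entities, columns become typed fields,
#' `NOT NULL` maps back to non-nillable, `UNIQUE` to unique, and foreign
#' keys to cross-references. Screen structure, labels, descriptions and
#' read-only flags are not recoverable from a schema (the documented
#' lossy set); extraction emits a skeleton ui — one list form per entity —
#' so the resulting application is immediately usable.
#'
#' @name extract-model
NULL

#' Introspect a relational schema
#'
#' Accepts a live handle (a [store_open()] store or a `DBI` connection), a
#' path to an SQLite database file, a path to a `.sql` DDL script, or DDL
#' text. Scripts are executed on a throwaway in-memory engine first, so
#' one code path reads every source.
#'
#' @param x schema source (see above)
#' @return a `ga_schema`: list of tables, each with `name`, a `columns`
#'   data frame (`name`, `sql_type`, `not_null`, `unique`) and an `fks`
#'   data frame (`column`, `ref_table`, `ref_column`); column order is
#'   table order
#' @export
introspect <- function(x) {
  if (inherits(x, "ga_store")) return(introspect_connection(x$con))
  if (inherits(x, "DBIConnection")) return(introspect_connection(x))
  if (!is.character(x) || length(x) != 1)
    ga_stop("EXTRACT_IO_ERROR", "unsupported schema source")
  if (file.exists(x) && !grepl("\\.sql$", x, ignore.case = TRUE)) {
    con <- tryCatch(DBI::dbConnect(RSQLite::SQLite(), x),
                    error = function(e)
                      ga_stop("EXTRACT_IO_ERROR", conditionMessage(e)))
    on.exit(DBI::dbDisconnect(con), add = TRUE)
    # a non-database file fails on the first catalogue query
    return(tryCatch(introspect_connection(con),
                    error = function(e)
                      ga_stop("EXTRACT_IO_ERROR", conditionMessage(e))))
  }
  ddl <- if (file.exists(x)) paste(readLines(x, warn = FALSE), collapse = "\n")
         else x
  if (!grepl("CREATE\\s+TABLE", ddl, ignore.case = TRUE) &&
      nzchar(trimws(ddl)) && !file.exists(x))
    ga_stop("EXTRACT_IO_ERROR",
            "input is neither a readable database/script nor DDL text")
  con <- DBI::dbConnect(RSQLite::SQLite(), ":memory:")
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  for (stmt in sql_statements(ddl)) {
    tryCatch(DBI::dbExecute(con, stmt),
             error = function(e)
               ga_stop("EXTRACT_IO_ERROR",
                       sprintf("DDL failed to execute: %s",
                               conditionMessage(e))))
  }
  introspect_connection(con)
}

introspect_connection <- function(con) {
  tables <- DBI::dbGetQuery(con,
    "SELECT name FROM sqlite_master WHERE type = 'table'
       AND name NOT LIKE 'sqlite_%' ORDER BY rowid")$name
  out <- lapply(tables, function(tbl) {
    info <- DBI::dbGetQuery(con, sprintf("PRAGMA table_info(%s)",
                                         DBI::dbQuoteIdentifier(con, tbl)))
    uniq <- unique_columns(con, tbl)
    cols <- data.frame(name = info$name,
                       sql_type = info$type,
                       not_null = info$notnull == 1 | info$pk > 0,
                       unique = tolower(info$name) %in% tolower(uniq) |
                         info$pk > 0,
                       stringsAsFactors = FALSE)
    fk <- DBI::dbGetQuery(con, sprintf("PRAGMA foreign_key_list(%s)",
                                       DBI::dbQuoteIdentifier(con, tbl)))
    fks <- if (nrow(fk) == 0)
      data.frame(id = integer(), column = character(),
                 ref_table = character(), ref_column = character(),
                 stringsAsFactors = FALSE)
    else data.frame(id = fk$id, column = fk$from, ref_table = fk$table,
                    ref_column = fk$to, stringsAsFactors = FALSE)
    list(name = tbl, columns = cols, fks = fks)
  })
  structure(list(tables = out), class = "ga_schema")
}

# single-column unique indexes (incl. those behind UNIQUE constraints)
unique_columns <- function(con, tbl) {
  idx <- DBI::dbGetQuery(con, sprintf("PRAGMA index_list(%s)",
                                      DBI::dbQuoteIdentifier(con, tbl)))
  if (nrow(idx) == 0) return(character())
  out <- character()
  for (i in seq_len(nrow(idx))) {
    if (idx$unique[i] != 1) next
    cols <- DBI::dbGetQuery(con, sprintf("PRAGMA index_info(%s)",
                                         DBI::dbQuoteIdentifier(con, idx$name[i])))
    if (nrow(cols) == 1) out <- c(out, cols$name)
  }
  out
}

# inverse of the forward SQL type map
inverse_sql_type <- function(sql) {
  s <- toupper(trimws(sql))
  m <- regmatches(s, regexec("^(VARCHAR|CHARACTER VARYING|CHAR|CHARACTER)\\s*\\((\\d+)\\)$", s))[[1]]
  if (length(m) > 0)
    return(list(type = "string", max_length = as.integer(m[3])))
  if (s %in% c("TEXT", "CLOB")) return(list(type = "text"))
  if (s %in% c("INT", "INTEGER", "BIGINT", "SMALLINT", "TINYINT"))
    return(list(type = "int"))
  if (s %in% c("DOUBLE PRECISION", "DOUBLE", "REAL", "FLOAT", "NUMERIC",
               "DECIMAL"))
    return(list(type = "decimal"))
  if (s == "BOOLEAN") return(list(type = "bool"))
  if (s == "DATE") return(list(type = "date"))
  NULL
}

#' Convert an introspected schema into a model
#'
#' The inverse of the schema generator's mapping, degrading gracefully:
#' an unmappable column type becomes a string field with an
#' `EXTRACT_TYPE_UNMAPPED` warning; a foreign key onto a non-unique
#' column promotes the target to unique with `EXTRACT_UNIQUE_PROMOTED`;
#' a composite foreign key is dropped (`EXTRACT_FK_COMPOSITE`) and its
#' columns imported as plain fields. The returned model always passes
#' [validate_model()].
#'
#' @param schema a [introspect()] result
#' @param name model name for the extracted application
#' @return `list(model = ga_model, issues = data.frame)` where `issues`
#'   holds warnings about lossy or degraded mappings
#' @export
to_model <- function(schema, name = "extracted") {
  issues <- list()
  warn <- function(code, locus, message)
    issues[[length(issues) + 1L]] <<- ga_issue("warning", code, locus, message)

  # fk lookup and composite detection per table
  entities <- list()
  promoted <- character()  # "table.column" promoted to unique
  for (tbl in schema$tables) {
    fks <- tbl$fks
    composite_ids <- unique(fks$id[duplicated(fks$id)])
    if (length(composite_ids) > 0) {
      warn("EXTRACT_FK_COMPOSITE", tbl$name,
           sprintf("%d composite foreign key(s) on '%s' imported as plain fields",
                   length(composite_ids), tbl$name))
      fks <- fks[!fks$id %in% composite_ids, , drop = FALSE]
    }
    fields <- list()
    for (i in seq_len(nrow(tbl$columns))) {
      col <- tbl$columns[i, ]
      fk <- fks[tolower(fks$column) == tolower(col$name), , drop = FALSE]
      if (nrow(fk) == 1) {
        target <- Find(function(t) tolower(t$name) == tolower(fk$ref_table),
                       schema$tables)
        ref_col <- if (!is.null(target))
          target$columns[tolower(target$columns$name) ==
                           tolower(fk$ref_column), , drop = FALSE]
        ref_is_fk <- !is.null(target) &&
          any(tolower(target$fks$column) == tolower(fk$ref_column))
        self_required <- tolower(fk$ref_table) == tolower(tbl$name) &&
          col$not_null
        if (ref_is_fk || self_required) {
          # a reference chain or a never-satisfiable self reference cannot
          # be represented; keep the column, drop the link
          warn("EXTRACT_FK_DEGRADED", paste0(tbl$name, ".", col$name),
               sprintf("foreign key on '%s.%s' cannot map to a cross-reference; imported as plain field",
                       tbl$name, col$name))
        } else if (!is.null(target) && nrow(ref_col) == 1) {
          if (!ref_col$unique) {
            warn("EXTRACT_UNIQUE_PROMOTED",
                 paste0(fk$ref_table, ".", fk$ref_column),
                 sprintf("foreign key target '%s.%s' promoted to unique",
                         fk$ref_table, fk$ref_column))
            promoted <- c(promoted,
                          tolower(paste0(fk$ref_table, ".", fk$ref_column)))
          }
          fields[[length(fields) + 1L]] <- ga_field(
            col$name, type = "xref", nillable = !col$not_null,
            unique = col$unique,
            xref_entity = target$name, xref_field = ref_col$name)
          next
        }
      }
      mapped <- inverse_sql_type(col$sql_type)
      if (is.null(mapped)) {
        warn("EXTRACT_TYPE_UNMAPPED", paste0(tbl$name, ".", col$name),
             sprintf("SQL type '%s' has no model equivalent; imported as string",
                     col$sql_type))
        mapped <- list(type = "string", max_length = 255L)
      }
      fields[[length(fields) + 1L]] <- ga_field(
        col$name, type = mapped$type,
        max_length = mapped$max_length %||% NA_integer_,
        nillable = !col$not_null, unique = col$unique)
    }
    entities[[length(entities) + 1L]] <- ga_entity(tbl$name, fields = fields)
  }

  # apply unique promotions
  entities <- lapply(entities, function(e) {
    e$fields <- lapply(e$fields, function(f) {
      if (tolower(paste0(e$name, ".", f$name)) %in% promoted) f$unique <- TRUE
      f
    })
    e
  })

  # every entity needs a key; promote the first column of keyless tables
  entities <- lapply(entities, function(e) {
    if (!any(vapply(e$fields, function(f) isTRUE(f$unique), NA)) &&
        length(e$fields) > 0) {
      warn("EXTRACT_UNIQUE_PROMOTED", paste0(e$name, ".", e$fields[[1]]$name),
           sprintf("table '%s' has no unique column; '%s' promoted to key",
                   e$name, e$fields[[1]]$name))
      e$fields[[1]]$unique <- TRUE
    }
    e
  })

  # skeleton ui: one list form per entity so the app is browsable
  ui <- lapply(entities, function(e)
    ga_ui("form", name = paste0(e$name, "s"), entity = e$name,
          view_mode = "list"))
  model <- resolve_inheritance(apply_defaults(
    ga_model(name, entities = entities, ui = ui)))
  list(model = model,
       issues = if (length(issues) == 0) ga_no_issues()
                else do.call(rbind, issues))
}

#' Extract a model file from an existing database or DDL script
#'
#' Convenience wrapper: [introspect()] then [to_model()], optionally
#' writing the canonical model XML.
#'
#' @inheritParams introspect
#' @param out optional path to write the model XML to
#' @param name model name
#' @return as [to_model()], plus `xml` (the serialized model)
#' @export
extract_model <- function(x, out = NULL, name = "extracted") {
  res <- to_model(introspect(x), name = name)
  res$xml <- serialize_model(res$model)
  if (!is.null(out)) writeLines(res$xml, out)
  res
}
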