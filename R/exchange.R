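#' @title Tab-delimited data exchange
#'
#' @description
#' Batch upload and download tailored to a model: the header row of a
#' `.tsv` file names model fields, cross-reference cells carry the
#' referenced row's key value, and a batch import walks files in
#' [entity_load_order()] so every reference can resolve. The dialect is
#' UTF-8, tab-separated, first line = header, CSV-style double-quote
#' escaping when a cell contains a tab, newline or quote; an empty cell
#' encodes NULL while the literal string `"null"` is just text.
#'
#' @name data-exchange
NULL

#' A tabular exchange file in memory
#' @param entity entity name the rows belong to
#' @param header character vector of field names
#' @param rows data frame of character cells (one column per header name)
#' @return a `ga_tabfile`
#' @export
ga_tabfile <- function(entity, header, rows) {
  stopifnot(identical(names(rows), header))
  structure(list(entity = entity, header = header, rows = rows),
            class = "ga_tabfile")
}

#' Read a `.tsv` exchange file
#' @param path file path (`.tsv` or `.txt`)
#' @param entity entity name the file holds (defaults to the file stem)
#' @return a [ga_tabfile()]
#' @export
read_tabfile <- function(path, entity = NULL) {
  if (is.null(entity))
    entity <- tools::file_path_sans_ext(basename(path))
  rows <- utils::read.delim(path, sep = "\t", header = TRUE,
                            colClasses = "character", na.strings = NULL,
                            quote = "\"", check.names = FALSE,
                            stringsAsFactors = FALSE)
  ga_tabfile(entity, names(rows), rows)
}

#' Write a `.tsv` exchange file
#' @param file a [ga_tabfile()]
#' @param path destination path
#' @return `path`, invisibly
#' @export
write_tabfile <- function(file, path) {
  data.table::fwrite(data.table::as.data.table(file$rows), path,
                     sep = "\t", quote = "auto", qmethod = "double",
                     na = "", col.names = TRUE)
  invisible(path)
}

#' Export all rows of an entity
#'
#' The header carries every flattened field in model order; rows are
#' sorted by the entity's key (first unique field); empty cells encode
#' NULL; xref cells hold the referenced row's key value.
#'
#' @inheritParams ga_find
#' @return a [ga_tabfile()]
#' @export
export_entity <- function(store, entity) {
  e <- store_entity(store, entity)
  res <- ga_find(store, e)
  cols <- lapply(e$fields, function(f) {
    vapply(seq_len(nrow(res$records)), function(i) {
      format_cell(res$records[[f$name]][i], f, store$model)
    }, "")
  })
  rows <- as.data.frame(stats::setNames(cols, field_names(e)),
                        stringsAsFactors = FALSE, optional = TRUE)
  if (res$total == 0)
    rows <- as.data.frame(stats::setNames(
      replicate(length(e$fields), character(0), simplify = FALSE),
      field_names(e)), stringsAsFactors = FALSE, optional = TRUE)
  ga_tabfile(e$name, field_names(e), rows)
}

#' Import one file into one entity
#'
#' Row-atomic, not file-atomic: every valid row is applied, every invalid
#' row is reported, so one pass over a large batch surfaces all
#' inconsistencies at once. A header column naming no model field rejects
#' the whole file (`IMPORT_UNKNOWN_COLUMN`), since it usually means the
#' file belongs to a different model version.
#'
#' @inheritParams ga_add
#' @param file a [ga_tabfile()]
#' @param mode `add` (new rows only), `update` (existing rows only) or the
#'   default `add_update` (upsert keyed on the entity's first unique field)
#' @param .defer optional internal hook: function(row_index, field, value)
#'   called instead of failing for an unresolvable nillable xref during a
#'   batch; the cell is imported as NULL and filled in a second pass
#' @return an `ga_import_report`: list with `entity`, `rows_added`,
#'   `rows_updated` and an `errors` data frame (`row`, `field`, `code`,
#'   `message`); `rows_added + rows_updated + nrow-of-error-rows` equals
#'   the input row count
#' @export
import_file <- function(store, entity, file, mode = "add_update",
                        .defer = NULL) {
  e <- store_entity(store, entity)
  mode <- match.arg(mode, c("add_update", "add", "update"))
  unknown <- setdiff(tolower(file$header), tolower(field_names(e)))
  if (length(unknown) > 0)
    ga_stop("IMPORT_UNKNOWN_COLUMN",
            sprintf("column(s) %s match no field of entity '%s'",
                    paste0("'", unknown, "'", collapse = ", "), e$name))
  kf <- key_field(e)
  if (!tolower(kf$name) %in% tolower(file$header))
    ga_stop("IMPORT_KEY_MISSING",
            sprintf("file for '%s' must carry key column '%s'",
                    e$name, kf$name))
  added <- 0L; updated <- 0L
  errors <- list()
  err <- function(row, field, code, message)
    errors[[length(errors) + 1L]] <<-
      data.frame(row = row, field = field, code = code, message = message,
                 stringsAsFactors = FALSE)
  seen_keys <- character()
  for (i in seq_len(nrow(file$rows))) {
    key_text <- file$rows[[match(tolower(kf$name),
                                 tolower(file$header))]][i]
    if (tolower(key_text) %in% seen_keys) {
      err(i, kf$name, "DUPLICATE_KEY",
          sprintf("key '%s' occurs more than once in the file", key_text))
      next
    }
    record <- list(); bad <- FALSE; deferred <- list()
    for (j in seq_along(file$header)) {
      f <- find_field(e, file$header[j])
      cell <- file$rows[[j]][i]
      v <- tryCatch(parse_cell(cell, f, store$model),
                    genapp_error = function(cond) cond)
      if (inherits(v, "condition")) {
        err(i, f$name, error_code(v), conditionMessage(v)); bad <- TRUE
        break
      }
      if (identical(f$type, "xref") && !is.na(v)) {
        ok <- tryCatch({ check_xref_resolves(store, f, v); TRUE },
                       genapp_error = function(cond) cond)
        if (inherits(ok, "condition")) {
          if (!is.null(.defer) && isTRUE(f$nillable)) {
            deferred[[f$name]] <- v
            v <- NA
          } else {
            err(i, f$name, error_code(ok), conditionMessage(ok)); bad <- TRUE
            break
          }
        }
      }
      record[[f$name]] <- v
    }
    if (bad) next
    key_val <- record[[kf$name]]
    exists <- tryCatch({ ga_get(store, e, key_val); TRUE },
                       genapp_error = function(cond) FALSE)
    outcome <- tryCatch({
      if (exists) {
        if (identical(mode, "add"))
          ga_stop("DUPLICATE_KEY",
                  sprintf("%s '%s' already exists", e$name, key_val))
        ga_update(store, e, key_val, record[setdiff(names(record), kf$name)])
        "updated"
      } else {
        if (identical(mode, "update"))
          ga_stop("NOT_FOUND",
                  sprintf("%s '%s' does not exist", e$name, key_val))
        ga_add(store, e, record)
        "added"
      }
    }, genapp_error = function(cond) cond)
    if (inherits(outcome, "condition")) {
      err(i, kf$name, error_code(outcome), conditionMessage(outcome))
      next
    }
    seen_keys <- c(seen_keys, tolower(as.character(key_text)))
    if (identical(outcome, "added")) added <- added + 1L else updated <- updated + 1L
    for (fn in names(deferred)) .defer(key_val, fn, deferred[[fn]])
  }
  structure(list(entity = e$name, rows_added = added, rows_updated = updated,
                 errors = if (length(errors) == 0)
                   data.frame(row = integer(), field = character(),
                              code = character(), message = character(),
                              stringsAsFactors = FALSE)
                 else do.call(rbind, errors)),
            class = "ga_import_report")
}

#' @export
print.ga_import_report <- function(x, ...) {
  cat(sprintf("<import %s> added %d, updated %d, errors %d\n",
              x$entity, x$rows_added, x$rows_updated, nrow(x$errors)))
  invisible(x)
}

#' Import a set of files in load order
#'
#' Files are processed in [entity_load_order()] so cross-references
#' resolve; an unresolvable nillable xref cell (the soft edge of a
#' reference cycle, or a forward self-reference) is imported as NULL and
#' filled in a second pass once all rows exist.
#'
#' @inheritParams ga_add
#' @param files named list (entity name -> [ga_tabfile()])
#' @param mode passed through to [import_file()]
#' @return named list of import reports, in processing order
#' @export
import_batch <- function(store, files, mode = "add_update") {
  model <- store$model
  unknown <- setdiff(tolower(names(files)), tolower(entity_names(model)))
  if (length(unknown) > 0)
    ga_stop("IMPORT_UNKNOWN_ENTITY",
            sprintf("no entity for file(s): %s",
                    paste(unknown, collapse = ", ")))
  ord <- entity_load_order(model)
  ord <- ord[tolower(ord) %in% tolower(names(files))]
  reports <- list()
  deferred <- list()  # second-pass xref fills: entity/key/field/value
  for (nm in ord) {
    e <- find_entity(model, nm)
    file <- files[[match(tolower(nm), tolower(names(files)))]]
    hook <- function(key, field, value)
      deferred[[length(deferred) + 1L]] <<-
        list(entity = e$name, key = key, field = field, value = value)
    reports[[e$name]] <- import_file(store, e, file, mode = mode,
                                     .defer = hook)
  }
  for (d in deferred) {
    res <- tryCatch({
      ga_update(store, d$entity, d$key,
                stats::setNames(list(d$value), d$field))
      NULL
    }, genapp_error = function(cond) cond)
    if (!is.null(res)) {
      rep <- reports[[d$entity]]
      rep$errors <- rbind(rep$errors, data.frame(
        row = NA_integer_, field = d$field, code = error_code(res),
        message = conditionMessage(res), stringsAsFactors = FALSE))
      reports[[d$entity]] <- rep
    }
  }
  reports
}
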