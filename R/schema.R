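#' @title Relational schema generation
#'
#' @description
#' Maps a validated model to DDL for the embedded SQLite engine: one table
#' per entity, one typed column per flattened field, `NOT NULL` from
#' non-nillable, `UNIQUE` from unique, and a `FOREIGN KEY` per
#' cross-reference. `readonly` is deliberately not a schema concern; it is
#' enforced by the CRUD layer. Identifiers are restricted to
#' `[A-Za-z][A-Za-z0-9_]*` by validation, so statements carry bare names.
#'
#' @name schema-generation
NULL

# forward type map; extract_model inverts it
GA_SQL_TYPES <- c(text = "TEXT", int = "INTEGER", decimal = "DOUBLE PRECISION",
                  bool = "BOOLEAN", date = "DATE")

#' DDL type of a field
#'
#' `string` maps to `VARCHAR(max_length)`; an xref column takes the SQL
#' type of the referenced key field (one level only — a reference to
#' another xref field raises `SCHEMA_XREF_CHAIN`).
#'
#' @param field a default-filled [ga_field()]
#' @param model the model, required for xref fields to look up the target
#' @return DDL type text, e.g. `"VARCHAR(255)"`
#' @export
sql_type <- function(field, model = NULL) {
  if (identical(field$type, "string"))
    return(sprintf("VARCHAR(%d)", field$max_length))
  if (identical(field$type, "xref")) {
    if (is.null(model))
      ga_stop("SCHEMA_XREF_CHAIN", "xref type lookup requires the model")
    target <- find_entity(model, field$xref_entity)
    tf <- if (!is.null(target)) find_field(target, field$xref_field)
    if (is.null(tf))
      ga_stop("XREF_TARGET_MISSING",
              sprintf("xref target %s.%s not found",
                      field$xref_entity, field$xref_field))
    if (identical(tf$type, "xref"))
      ga_stop("SCHEMA_XREF_CHAIN",
              sprintf("field '%s' references xref field '%s.%s'; chains are unsupported",
                      field$name, field$xref_entity, field$xref_field))
    return(sql_type(tf, model))
  }
  out <- GA_SQL_TYPES[[field$type]]
  if (is.null(out))
    ga_stop("FIELD_BAD_TYPE", sprintf("no SQL mapping for type '%s'", field$type))
  out
}

#' CREATE TABLE statement for one entity
#'
#' @param entity a flattened [ga_entity()]
#' @param model the containing model (for xref type/target lookup)
#' @return one DDL statement as text, `;`-terminated
#' @export
create_table_ddl <- function(entity, model) {
  cols <- vapply(entity$fields, function(f) {
    paste0("  ", f$name, " ", sql_type(f, model),
           if (!isTRUE(f$nillable)) " NOT NULL" else "",
           if (isTRUE(f$unique)) " UNIQUE" else "")
  }, "")
  fks <- vapply(xref_fields(entity), function(f) {
    target <- find_entity(model, f$xref_entity)
    sprintf("  FOREIGN KEY (%s) REFERENCES %s (%s)",
            f$name, target$name, find_field(target, f$xref_field)$name)
  }, "")
  paste0("CREATE TABLE ", entity$name, " (\n",
         paste(c(cols, fks), collapse = ",\n"),
         "\n);")
}

#' Full DDL script for a model
#'
#' Statements are emitted in [entity_load_order()], so every referenced
#' table exists before its referrers and the script executes cleanly on
#' the embedded engine.
#'
#' @param model a valid, resolved [ga_model()]
#' @return the DDL script as a single string (possibly empty)
#' @export
schema_ddl <- function(model) {
  assert_valid(model, code = "GENERATE_INVALID_MODEL")
  ord <- entity_load_order(model)
  stmts <- vapply(ord, function(nm) {
    create_table_ddl(find_entity(model, nm), model)
  }, "")
  paste(stmts, collapse = "\n\n")
}
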