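#' @title Entity-model data structures
#'
#' @description
#' The modeling language describes an experiment database as a set of
#' *entities* (data types such as Experiment or Sample) with typed *fields*,
#' plus a declarative *ui* section (menus, forms, plugins). These
#' constructors build the in-memory representation; attributes a model file
#' left unset are `NA` until [apply_defaults()] fills them with their
#' convention value.
#'
#' @name model-structures
NULL

GA_FIELD_TYPES <- c("string", "text", "int", "decimal", "bool", "date", "xref")
GA_NAME_RE <- "^[A-Za-z][A-Za-z0-9_]*$"

#' Construct a field
#'
#' @param name field identifier
#' @param type one of `string, text, int, decimal, bool, date, xref`
#'   (`NA` = unset, defaults to `string`)
#' @param nillable may the field be empty (`NA` = unset, defaults `FALSE`)
#' @param readonly may the field change after creation (`NA` = unset,
#'   defaults `FALSE`)
#' @param unique must values be unique across rows (`NA` = unset, defaults
#'   `FALSE`)
#' @param max_length maximum string length (string type only; `NA` = unset,
#'   defaults 255)
#' @param xref_entity,xref_field target of a cross-reference (xref type only)
#' @param description free text
#' @param default_value optional literal used when an import leaves the cell
#'   empty
#' @return a `ga_field`
#' @export
ga_field <- function(name, type = NA_character_, nillable = NA,
                     readonly = NA, unique = NA, max_length = NA_integer_,
                     xref_entity = NA_character_, xref_field = NA_character_,
                     description = NA_character_,
                     default_value = NA_character_) {
  structure(list(
    name = name, type = type, nillable = nillable, readonly = readonly,
    unique = unique,
    max_length = if (is.na(max_length)) NA_integer_ else as.integer(max_length),
    xref_entity = xref_entity, xref_field = xref_field,
    description = description, default_value = default_value,
    inherited_from = NA_character_
  ), class = "ga_field")
}

#' Construct an entity
#'
#' @param name entity identifier
#' @param label display label (`NA` = unset, defaults to `name`)
#' @param description free text
#' @param extends optional parent entity name (single inheritance; the
#'   child's effective field list is the parent's fields followed by its own)
#' @param fields list of [ga_field()] in declaration order
#' @return a `ga_entity`
#' @export
ga_entity <- function(name, label = NA_character_,
                      description = NA_character_,
                      extends = NA_character_, fields = list()) {
  structure(list(name = name, label = label, description = description,
                 extends = extends, fields = fields),
            class = "ga_entity")
}

#' Construct a user-interface element
#'
#' Menus group screens, forms show one entity (one record per screen by
#' default, or as a list), and plugins name extension points where
#' hand-written components mount. A form nested under another form is a
#' *child form*: its rows are filtered to the parent's selected record via
#' the cross-reference connecting their entities.
#'
#' @param kind one of `menu`, `form`, `plugin`
#' @param name element identifier (unique among siblings)
#' @param entity entity shown (form only)
#' @param view_mode `record` or `list` (form only; `NA` = unset, defaults
#'   `record`)
#' @param plugin_id extension-point identifier (plugin only)
#' @param link_field explicit xref field linking a child form to its parent
#'   form's entity; normally auto-derived
#' @param children nested elements (menu and form)
#' @return a `ga_ui`
#' @export
ga_ui <- function(kind, name, entity = NA_character_,
                  view_mode = NA_character_, plugin_id = NA_character_,
                  link_field = NA_character_, children = list()) {
  structure(list(kind = kind, name = name, entity = entity,
                 view_mode = view_mode, plugin_id = plugin_id,
                 link_field = link_field, children = children),
            class = "ga_ui")
}

#' Construct a model
#'
#' @param name short identifier for the application
#' @param entities list of [ga_entity()] in declaration order
#' @param ui list of top-level [ga_ui()] elements
#' @return a `ga_model`
#' @export
ga_model <- function(name, entities = list(), ui = list()) {
  structure(list(name = name, entities = entities, ui = ui),
            class = "ga_model")
}

#' @export
print.ga_model <- function(x, ...) {
  cat(sprintf("<ga_model> %s: %d entities, %d top-level ui elements\n",
              x$name, length(x$entities), length(x$ui)))
  for (e in x$entities) {
    cat(sprintf("  %s%s (%d fields)\n", e$name,
                if (!is.na(e$extends)) paste0(" extends ", e$extends) else "",
                length(e$fields)))
  }
  invisible(x)
}

#' @export
print.ga_entity <- function(x, ...) {
  cat(sprintf("<ga_entity> %s (%d fields)\n", x$name, length(x$fields)))
  invisible(x)
}

# --- lookup helpers (case-insensitive matching, names stored as declared) ---

#' Model accessors
#'
#' Small lookup helpers over models and entities. Name matching is
#' case-insensitive; names are stored as declared.
#'
#' @param model a [ga_model()]
#' @param entity a [ga_entity()]
#' @param name an entity or field name
#' @return `entity_names()`/`field_names()` return character vectors in
#'   declaration order; `find_entity()`/`find_field()` the matching object
#'   or `NULL`; `key_field()` the entity's first unique field (the key rows
#'   are identified by) or `NULL`; `xref_fields()` the entity's
#'   cross-reference fields.
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
entity_names <- function(model) vapply(model$entities, `[[`, "", "name")

#' @rdname model-accessors
#' @export
find_entity <- function(model, name) {
  idx <- match(tolower(name), tolower(entity_names(model)))
  if (is.na(idx)) NULL else model$entities[[idx]]
}

#' @rdname model-accessors
#' @export
field_names <- function(entity) vapply(entity$fields, `[[`, "", "name")

#' @rdname model-accessors
#' @export
find_field <- function(entity, name) {
  idx <- match(tolower(name), tolower(field_names(entity)))
  if (is.na(idx)) NULL else entity$fields[[idx]]
}

#' @rdname model-accessors
#' @export
key_field <- function(entity) {
  for (f in entity$fields) if (isTRUE(f$unique)) return(f)
  NULL
}

#' @rdname model-accessors
#' @export
xref_fields <- function(entity) {
  Filter(function(f) identical(f$type, "xref"), entity$fields)
}

defaults_applied <- function(model) isTRUE(attr(model, "defaults_applied"))
inheritance_resolved <- function(model) isTRUE(attr(model, "resolved"))
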