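#' Fill unset model attributes with their convention values
#'
#' Convention over configuration: a model author only writes what deviates
#' from the sensible default, everything else is filled in here. The
#' conventions are: field `type` = `string`; a string's `max_length` = 255;
#' `nillable` = `FALSE` (a value is required); `readonly` = `FALSE`
#' (editable); `unique` = `FALSE`; entity and ui `label` = the declared
#' name; form `view_mode` = `record` (one record per screen).
#'
#' The operation is idempotent and never overwrites an explicitly set
#' attribute.
#'
#' @param model a parsed [ga_model()]
#' @return the model with every attribute set and `defaults_applied` marked
#' @export
apply_defaults <- function(model) {
  model$entities <- lapply(model$entities, function(e) {
    if (is.na(e$label)) e$label <- e$name
    e$fields <- lapply(e$fields, default_fill_field)
    e
  })
  model$ui <- lapply(model$ui, default_fill_ui)
  attr(model, "defaults_applied") <- TRUE
  model
}

default_fill_field <- function(f) {
  if (is.na(f$type)) f$type <- "string"
  if (identical(f$type, "string") && is.na(f$max_length))
    f$max_length <- 255L
  if (is.na(f$nillable)) f$nillable <- FALSE
  if (is.na(f$readonly)) f$readonly <- FALSE
  if (is.na(f$unique)) f$unique <- FALSE
  f
}

default_fill_ui <- function(el) {
  if (identical(el$kind, "form") && is.na(el$view_mode))
    el$view_mode <- "record"
  el$children <- lapply(el$children, default_fill_ui)
  el
}

#' Flatten entity inheritance
#'
#' Each entity's effective field list becomes its parent's flattened fields
#' (in order) followed by its own fields. The `extends` marker is retained
#' for documentation and serialization; inherited fields are tagged with
#' their defining ancestor so [serialize_model()] can emit only the fields
#' an entity declared itself.
#'
#' @param model a model with defaults applied
#' @return the model with flattened field lists and `resolved` marked
#' @export
resolve_inheritance <- function(model) {
  if (!defaults_applied(model))
    ga_stop("MODEL_STATE", "apply_defaults() must run before resolve_inheritance()")
  nms <- entity_names(model)
  flat_cache <- list()

  flatten <- function(name, trail = character()) {
    lname <- tolower(name)
    if (!is.null(flat_cache[[lname]])) return(flat_cache[[lname]])
    if (lname %in% tolower(trail))
      ga_stop("MODEL_INHERITANCE_CYCLE",
              paste("inheritance cycle:",
                    paste(c(trail, name), collapse = " -> ")))
    e <- find_entity(model, name)
    if (is.null(e))
      ga_stop("MODEL_PARENT_MISSING",
              sprintf("entity '%s' extends unknown entity '%s'",
                      trail[length(trail)], name))
    inherited <- list()
    if (!is.na(e$extends)) {
      parent_fields <- flatten(e$extends, c(trail, name))
      inherited <- lapply(parent_fields, function(f) {
        if (is.na(f$inherited_from)) f$inherited_from <- e$extends
        f
      })
    }
    own_names <- tolower(vapply(e$fields, `[[`, "", "name"))
    inh_names <- tolower(vapply(inherited, `[[`, "", "name"))
    dup <- intersect(own_names, inh_names)
    if (length(dup) > 0)
      ga_stop("FIELD_REDECLARED",
              sprintf("entity '%s' redeclares inherited field(s): %s",
                      e$name, paste(dup, collapse = ", ")))
    flat <- c(inherited, e$fields)
    flat_cache[[lname]] <<- flat
    flat
  }

  model$entities <- lapply(model$entities, function(e) {
    e$fields <- flatten(e$name)
    e
  })
  attr(model, "resolved") <- TRUE
  model
}

# own (non-inherited) fields of a resolved entity
own_fields <- function(entity) {
  Filter(function(f) is.na(f$inherited_from), entity$fields)
}

#' Parse, default-fill and flatten a model file in one step
#'
#' Convenience wrapper chaining [parse_model()], [apply_defaults()] and
#' [resolve_inheritance()].
#'
#' @inheritParams parse_model
#' @return a resolved `ga_model`
#' @export
load_model <- function(xml_text, strict = TRUE) {
  resolve_inheritance(apply_defaults(parse_model(xml_text, strict = strict)))
}
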