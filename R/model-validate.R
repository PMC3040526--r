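#' Validate a model
#'
#' Checks every structural invariant of the modeling language on a
#' default-filled, inheritance-resolved model and returns the issues found
#' as a data frame (`severity`, `code`, `locus`, `message`), ordered by
#' model position. An empty frame means the model is valid. Codes are drawn
#' from a closed, documented enumeration (see Details).
#'
#' @details Issue codes:
#' \describe{
#'   \item{MODEL_DUPLICATE_ENTITY}{two entities share a name
#'     (case-insensitive)}
#'   \item{NAME_INVALID}{an identifier is not `[A-Za-z][A-Za-z0-9_]*`}
#'   \item{FIELD_REDECLARED}{duplicate field name within a flattened entity}
#'   \item{FIELD_BAD_TYPE / FIELD_BAD_LENGTH}{unknown field type; or
#'     `max_length` on a non-string / non-positive}
#'   \item{XREF_INCOMPLETE / XREF_ATTRS_UNEXPECTED}{xref target attributes
#'     missing on an xref field, or present on a non-xref field}
#'   \item{XREF_TARGET_MISSING / XREF_TARGET_NOT_UNIQUE / XREF_TO_XREF}{the
#'     referenced entity/field does not exist, is not unique-valued, or is
#'     itself an xref (chains are unsupported)}
#'   \item{XREF_SELF_NOT_NILLABLE}{a self-reference must be nillable,
#'     otherwise no row could ever be inserted}
#'   \item{MODEL_XREF_CYCLE}{a cross-entity reference cycle with no nillable
#'     edge, which no load order could satisfy}
#'   \item{ENTITY_NO_KEY}{entity has no unique field to identify rows by}
#'   \item{UI_ENTITY_MISSING / UI_DUPLICATE_NAME / UI_NO_LINK /
#'     UI_AMBIGUOUS_LINK / UI_BAD_LINK_FIELD}{a form references an unknown
#'     entity; sibling names clash; a child form has no xref linking it to
#'     its parent form's entity, more than one candidate and no explicit
#'     `link_field`, or an explicit `link_field` that is not such an xref}
#' }
#'
#' @param model a resolved [ga_model()]
#' @return a data frame of issues; zero rows iff the model is valid
#' @export
validate_model <- function(model) {
  if (!inheritance_resolved(model))
    ga_stop("MODEL_STATE",
            "validate_model() requires apply_defaults() and resolve_inheritance()")
  issues <- list()
  add <- function(severity, code, locus, message)
    issues[[length(issues) + 1L]] <<- ga_issue(severity, code, locus, message)

  nms <- entity_names(model)
  dup <- duplicated(tolower(nms))
  for (i in which(dup))
    add("error", "MODEL_DUPLICATE_ENTITY", nms[i],
        sprintf("entity name '%s' declared more than once", nms[i]))

  for (e in model$entities) {
    locus_e <- e$name
    if (!grepl(GA_NAME_RE, e$name))
      add("error", "NAME_INVALID", locus_e,
          sprintf("'%s' is not a valid identifier", e$name))
    fn <- field_names(e)
    for (i in which(duplicated(tolower(fn))))
      add("error", "FIELD_REDECLARED", paste0(locus_e, ".", fn[i]),
          sprintf("field '%s' declared more than once in '%s'", fn[i], e$name))
    if (is.null(key_field(e)))
      add("error", "ENTITY_NO_KEY", locus_e,
          sprintf("entity '%s' has no unique field to identify rows", e$name))
    for (f in e$fields) {
      locus_f <- paste0(locus_e, ".", f$name)
      if (!grepl(GA_NAME_RE, f$name))
        add("error", "NAME_INVALID", locus_f,
            sprintf("'%s' is not a valid identifier", f$name))
      if (!f$type %in% GA_FIELD_TYPES) {
        add("error", "FIELD_BAD_TYPE", locus_f,
            sprintf("unknown type '%s'", f$type))
        next
      }
      if (identical(f$type, "string")) {
        if (is.na(f$max_length) || f$max_length < 1L)
          add("error", "FIELD_BAD_LENGTH", locus_f,
              "string field needs max_length >= 1")
      } else if (!is.na(f$max_length)) {
        add("error", "FIELD_BAD_LENGTH", locus_f,
            sprintf("max_length is only valid on string fields, not %s", f$type))
      }
      if (identical(f$type, "xref")) {
        if (is.na(f$xref_entity) || is.na(f$xref_field)) {
          add("error", "XREF_INCOMPLETE", locus_f,
              "xref field needs both xref_entity and xref_field")
          next
        }
        target <- find_entity(model, f$xref_entity)
        if (is.null(target)) {
          add("error", "XREF_TARGET_MISSING", locus_f,
              sprintf("xref target entity '%s' does not exist", f$xref_entity))
          next
        }
        tf <- find_field(target, f$xref_field)
        if (is.null(tf)) {
          add("error", "XREF_TARGET_MISSING", locus_f,
              sprintf("xref target field '%s.%s' does not exist",
                      f$xref_entity, f$xref_field))
          next
        }
        if (identical(tf$type, "xref"))
          add("error", "XREF_TO_XREF", locus_f,
              "xref may not target another xref field")
        if (!isTRUE(tf$unique))
          add("error", "XREF_TARGET_NOT_UNIQUE", locus_f,
              sprintf("xref target '%s.%s' must be declared unique",
                      f$xref_entity, f$xref_field))
        if (tolower(f$xref_entity) == tolower(e$name) && !isTRUE(f$nillable))
          add("error", "XREF_SELF_NOT_NILLABLE", locus_f,
              "a self-referencing xref must be nillable")
      } else if (!is.na(f$xref_entity) || !is.na(f$xref_field)) {
        add("error", "XREF_ATTRS_UNEXPECTED", locus_f,
            sprintf("xref_entity/xref_field are only valid on xref fields, not %s",
                    f$type))
      }
    }
  }

  # a reference cycle with no nillable edge cannot be loaded in any order
  cyc <- hard_xref_cycle(model)
  if (!is.null(cyc))
    add("error", "MODEL_XREF_CYCLE", cyc[1],
        sprintf("cross-reference cycle with no nillable edge: %s",
                paste(cyc, collapse = " -> ")))

  for (iss in validate_ui(model)) issues[[length(issues) + 1L]] <- iss

  if (length(issues) == 0) ga_no_issues() else do.call(rbind, issues)
}

validate_ui <- function(model) {
  issues <- list()
  add <- function(severity, code, locus, message)
    issues[[length(issues) + 1L]] <<- ga_issue(severity, code, locus, message)

  walk <- function(elements, parent_entity, path) {
    nms <- vapply(elements, `[[`, "", "name")
    for (i in which(duplicated(tolower(nms))))
      add("error", "UI_DUPLICATE_NAME", paste0(path, "/", nms[i]),
          sprintf("ui element name '%s' repeated among siblings", nms[i]))
    for (el in elements) {
      locus <- paste0(path, "/", el$name)
      if (identical(el$kind, "form")) {
        entity <- find_entity(model, el$entity)
        if (is.null(entity)) {
          add("error", "UI_ENTITY_MISSING", locus,
              sprintf("form '%s' references unknown entity '%s'",
                      el$name, el$entity))
          walk(el$children, NA_character_, locus)
          next
        }
        if (!is.na(parent_entity)) {
          link <- resolve_form_link(model, entity, parent_entity, el$link_field)
          if (!is.null(link$issue))
            add("error", link$issue, locus, link$message)
        }
        walk(el$children, entity$name, locus)
      } else {
        walk(el$children, parent_entity, locus)
      }
    }
  }
  walk(model$ui, NA_character_, "ui")
  issues
}

# find the xref field of `entity` that links a child form to a parent form
# showing `parent_entity`; an explicit link_field overrides auto-derivation
resolve_form_link <- function(model, entity, parent_entity, link_field) {
  candidates <- Filter(
    function(f) !is.na(f$xref_entity) &&
      tolower(f$xref_entity) == tolower(parent_entity),
    xref_fields(entity))
  if (!is.na(link_field)) {
    f <- find_field(entity, link_field)
    if (is.null(f) || !identical(f$type, "xref") ||
        tolower(f$xref_entity) != tolower(parent_entity))
      return(list(issue = "UI_BAD_LINK_FIELD",
                  message = sprintf(
                    "link_field '%s' is not an xref of '%s' targeting '%s'",
                    link_field, entity$name, parent_entity)))
    return(list(field = f$name))
  }
  if (length(candidates) == 0)
    return(list(issue = "UI_NO_LINK",
                message = sprintf(
                  "no xref links entity '%s' to parent form entity '%s'",
                  entity$name, parent_entity)))
  if (length(candidates) > 1)
    return(list(issue = "UI_AMBIGUOUS_LINK",
                message = sprintf(
                  "%d xrefs link '%s' to '%s'; declare link_field",
                  length(candidates), entity$name, parent_entity)))
  list(field = candidates[[1]]$name)
}

#' Stop unless a model validates cleanly
#' @param model a resolved model
#' @param code error code to signal when validation fails
#' @return the model, invisibly
#' @keywords internal
assert_valid <- function(model, code = "GENERATE_INVALID_MODEL") {
  issues <- validate_model(model)
  errs <- issues[issues$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0)
    ga_stop(code, paste0("model has validation errors: ",
                         paste(sprintf("[%s] %s", errs$code, errs$locus),
                               collapse = "; ")),
            issues = issues)
  invisible(model)
}
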