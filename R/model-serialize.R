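#' Serialize a model to its canonical XML form
#'
#' Writes the model back to the modeling language. The form is canonical:
#' attributes equal to their convention default are omitted, and for a
#' resolved model only the fields an entity declared itself are written
#' (inherited fields are reproduced by `extends` on re-parse). Consequently
#' `parse_model(serialize_model(m))` is semantically equal to `m`, and two
#' semantically equal models serialize to identical text — the package's
#' structural-equality test ([model_equal()]) rests on this.
#'
#' @param model a [ga_model()] (raw or resolved)
#' @return the XML document as a single string
#' @export
serialize_model <- function(model) {
  doc <- xml2::xml_new_root("molgenis", name = model$name)
  for (e in model$entities) {
    at <- drop_na(c(name = e$name,
                    label = if (!is.na(e$label) && e$label != e$name) e$label,
                    description = na_null(e$description),
                    extends = na_null(e$extends)))
    en <- xml2::xml_add_child(doc, "entity")
    set_attrs(en, at)
    for (f in own_fields(e)) {
      fat <- drop_na(c(
        name = f$name,
        type = if (!is.na(f$type) && f$type != "string") f$type,
        length = if (!is.na(f$max_length) && f$max_length != 255L)
          as.character(f$max_length),
        nillable = if (isTRUE(f$nillable)) "true",
        readonly = if (isTRUE(f$readonly)) "true",
        unique = if (isTRUE(f$unique)) "true",
        xref_entity = na_null(f$xref_entity),
        xref_field = na_null(f$xref_field),
        default = na_null(f$default_value),
        description = na_null(f$description)))
      set_attrs(xml2::xml_add_child(en, "field"), fat)
    }
  }
  if (length(model$ui) > 0) {
    un <- xml2::xml_add_child(doc, "ui")
    for (el in model$ui) serialize_ui(un, el)
  }
  as.character(doc)
}

serialize_ui <- function(parent, el) {
  if (identical(el$kind, "menu")) {
    node <- xml2::xml_add_child(parent, "menu")
    set_attrs(node, c(name = el$name))
  } else if (identical(el$kind, "form")) {
    node <- xml2::xml_add_child(parent, "form")
    set_attrs(node, drop_na(c(
      name = el$name, entity = el$entity,
      view = if (!is.na(el$view_mode) && el$view_mode != "record") el$view_mode,
      link_field = na_null(el$link_field))))
  } else {
    node <- xml2::xml_add_child(parent, "plugin")
    set_attrs(node, c(name = el$name, id = el$plugin_id))
  }
  for (child in el$children) serialize_ui(node, child)
  invisible(node)
}

set_attrs <- function(node, at) {
  for (nm in names(at)) xml2::xml_set_attr(node, nm, at[[nm]])
}

na_null <- function(x) if (length(x) == 0 || is.na(x)) NULL else x
drop_na <- function(x) x[!is.na(x)]

#' Structural equality of two models
#'
#' Models are compared semantically: both are default-filled and
#' inheritance-resolved, then their canonical serializations compared.
#'
#' @param a,b models
#' @return `TRUE` or `FALSE`
#' @export
model_equal <- function(a, b) {
  canon <- function(m) {
    if (!defaults_applied(m)) m <- apply_defaults(m)
    if (!inheritance_resolved(m)) m <- resolve_inheritance(m)
    serialize_model(m)
  }
  identical(canon(a), canon(b))
}
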