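#' Parse a model file
#'
#' Reads the XML modeling language into a [ga_model()]. Parsing is *raw*:
#' only attributes literally present in the document are set, everything
#' else stays unset (`NA`) until [apply_defaults()] runs, so the
#' convention-over-configuration step is observable and idempotent.
#'
#' The vocabulary is:
#' \preformatted{
#' <molgenis name="app">
#'   <entity name="Experiment" label=".." description=".." extends="..">
#'     <field name="ID" type="string" unique="true" nillable="false"
#'            readonly="true" length="255" xref_entity=".." xref_field=".."
#'            default=".." description=".."/>
#'   </entity>
#'   <ui>
#'     <plugin name="header" id="ext.point.id"/>
#'     <menu name="main">
#'       <form name="Experiments" entity="Experiment" view="record|list"
#'             link_field="..">...child forms/menus...</form>
#'     </menu>
#'   </ui>
#' </molgenis>
#' }
#'
#' @param xml_text the document as a string, or a path to an `.xml` file
#' @param strict unknown elements or attributes are an error when `TRUE`
#'   (default); a warning when `FALSE`
#' @return a raw `ga_model` (defaults not yet applied)
#' @seealso [apply_defaults()], [resolve_inheritance()], [validate_model()]
#' @export
parse_model <- function(xml_text, strict = TRUE) {
  doc <- tryCatch(
    xml2::read_xml(xml_text),
    error = function(e) ga_stop("MODEL_PARSE_ERROR",
                                paste("malformed XML:", conditionMessage(e)))
  )
  root <- xml2::xml_name(doc)
  if (root != "molgenis")
    ga_stop("MODEL_PARSE_ERROR",
            sprintf("expected root element <molgenis>, found <%s>", root))
  check_attrs(doc, "molgenis", c("name"), strict)

  entities <- list()
  ui <- list()
  for (node in xml2::xml_children(doc)) {
    nm <- xml2::xml_name(node)
    if (nm == "entity") {
      entities[[length(entities) + 1L]] <- parse_entity(node, strict)
    } else if (nm == "ui") {
      check_attrs(node, "ui", character(), strict)
      for (child in xml2::xml_children(node)) {
        el <- parse_ui(child, strict)
        if (!is.null(el)) ui[[length(ui) + 1L]] <- el
      }
    } else {
      unknown_markup(node, strict)
    }
  }
  ga_model(name = attr_or(doc, "name", "unnamed"),
           entities = entities, ui = ui)
}

parse_entity <- function(node, strict) {
  check_attrs(node, "entity", c("name", "label", "description", "extends"),
              strict, required = "name")
  fields <- list()
  for (child in xml2::xml_children(node)) {
    if (xml2::xml_name(child) == "field") {
      fields[[length(fields) + 1L]] <- parse_field(child, strict)
    } else {
      unknown_markup(child, strict)
    }
  }
  ga_entity(name = attr_or(node, "name"),
            label = attr_or(node, "label"),
            description = attr_or(node, "description"),
            extends = attr_or(node, "extends"),
            fields = fields)
}

parse_field <- function(node, strict) {
  check_attrs(node, "field",
              c("name", "type", "nillable", "readonly", "unique", "length",
                "xref_entity", "xref_field", "default", "description"),
              strict, required = "name")
  if (length(xml2::xml_children(node)) > 0)
    unknown_markup(xml2::xml_children(node)[[1]], strict)
  len <- attr_or(node, "length")
  ga_field(name = attr_or(node, "name"),
           type = attr_or(node, "type"),
           nillable = attr_bool(node, "nillable"),
           readonly = attr_bool(node, "readonly"),
           unique = attr_bool(node, "unique"),
           max_length = if (is.na(len)) NA_integer_ else as.integer(len),
           xref_entity = attr_or(node, "xref_entity"),
           xref_field = attr_or(node, "xref_field"),
           description = attr_or(node, "description"),
           default_value = attr_or(node, "default"))
}

parse_ui <- function(node, strict) {
  nm <- xml2::xml_name(node)
  compact <- function(x) Filter(Negate(is.null), x)
  if (nm == "menu") {
    check_attrs(node, "menu", c("name"), strict, required = "name")
    kids <- compact(lapply(xml2::xml_children(node), parse_ui, strict = strict))
    ga_ui("menu", attr_or(node, "name"), children = kids)
  } else if (nm == "form") {
    check_attrs(node, "form", c("name", "entity", "view", "link_field"),
                strict, required = c("name", "entity"))
    kids <- compact(lapply(xml2::xml_children(node), parse_ui, strict = strict))
    ga_ui("form", attr_or(node, "name"),
          entity = attr_or(node, "entity"),
          view_mode = attr_or(node, "view"),
          link_field = attr_or(node, "link_field"),
          children = kids)
  } else if (nm == "plugin") {
    check_attrs(node, "plugin", c("name", "id"), strict,
                required = c("name", "id"))
    ga_ui("plugin", attr_or(node, "name"), plugin_id = attr_or(node, "id"))
  } else {
    unknown_markup(node, strict)
    # lax mode: unknown ui markup is skipped
    NULL
  }
}

attr_or <- function(node, name, default = NA_character_) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) default else v
}

attr_bool <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) return(NA)
  if (!v %in% c("true", "false"))
    ga_stop("MODEL_PARSE_ERROR",
            sprintf("attribute '%s' must be 'true' or 'false', got '%s' at %s",
                    name, v, xml2::xml_path(node)))
  v == "true"
}

check_attrs <- function(node, element, known, strict, required = character()) {
  present <- names(xml2::xml_attrs(node))
  extra <- setdiff(present, known)
  if (length(extra) > 0) {
    msg <- sprintf("unknown attribute(s) %s on <%s> at %s",
                   paste0("'", extra, "'", collapse = ", "), element,
                   xml2::xml_path(node))
    if (strict) ga_stop("MODEL_UNKNOWN_MARKUP", msg) else warning(msg, call. = FALSE)
  }
  missing <- setdiff(required, present)
  if (length(missing) > 0)
    ga_stop("MODEL_PARSE_ERROR",
            sprintf("<%s> at %s is missing required attribute(s) %s",
                    element, xml2::xml_path(node),
                    paste0("'", missing, "'", collapse = ", ")))
}

unknown_markup <- function(node, strict) {
  msg <- sprintf("unknown element <%s> at %s",
                 xml2::xml_name(node), xml2::xml_path(node))
  if (strict) ga_stop("MODEL_UNKNOWN_MARKUP", msg) else warning(msg, call. = FALSE)
  invisible(NULL)
}
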