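#' @title Template engine
#'
#' @description
#' Generators are plain-text templates whose variable parts are "holes"
#' written `${command(args)}`; at generation time every hole is filled
#' from the model. The command language is deliberately tiny and closed:
#'
#' \describe{
#'   \item{`Name(x)`}{declared name of an entity, field or the model}
#'   \item{`name(x)`}{the same, lowercased}
#'   \item{`label(x)`}{display label of an entity or field}
#'   \item{`type(x)`}{a field's model type}
#'   \item{`sql_type(x)`}{a field's DDL type}
#'   \item{`csv(list, cmd [, sep])`}{apply `cmd` to every element of
#'     `entity.fields` or `model.entities` and join with `sep`
#'     (default `","`)}
#' }
#'
#' Rendering is pure: the same template and model element always produce
#' the same text, and the output never contains residual hole delimiters.
#'
#' @name template-engine
NULL

GA_TEMPLATE_COMMANDS <- c("Name", "name", "label", "type", "sql_type", "csv")

#' Construct a template
#'
#' @param id identifier (provenance tag on generated files)
#' @param scope `"model"` (rendered once) or `"per_entity"` (rendered for
#'   each entity)
#' @param body template text with `${...}` holes
#' @param output_path_pattern relative output path; `${Name}` substitutes
#'   the element name
#' @return a `ga_template`
#' @export
ga_template <- function(id, scope = c("model", "per_entity"), body,
                        output_path_pattern) {
  scope <- match.arg(scope)
  tpl <- structure(list(id = id, scope = scope, body = body,
                        output_path_pattern = output_path_pattern),
                   class = "ga_template")
  for (h in find_holes(body)) parse_hole(h)  # fail fast on unknown commands
  tpl
}

#' Load a template from a file
#' @param path template file; the id is the file stem without `.tmpl`
#' @inheritParams ga_template
#' @return a `ga_template`
#' @export
read_template <- function(path, scope, output_path_pattern) {
  body <- paste(readLines(path, warn = FALSE), collapse = "\n")
  ga_template(tools::file_path_sans_ext(basename(path)), scope, body,
              output_path_pattern)
}

# all ${...} holes in a body, in order
find_holes <- function(body) {
  m <- gregexpr("\\$\\{[^}]*\\}", body)[[1]]
  if (m[1] == -1) return(character())
  vapply(seq_along(m), function(i) {
    substr(body, m[i] + 2L, m[i] + attr(m, "match.length")[i] - 2L)
  }, "")
}

# "csv(entity.fields, name, ;)" -> list(cmd, args)
parse_hole <- function(hole) {
  m <- regmatches(hole, regexec("^\\s*(\\w+)\\s*\\(([^)]*)\\)\\s*$", hole))[[1]]
  if (length(m) == 0)
    ga_stop("TEMPLATE_BAD_ARGS", sprintf("malformed hole '${%s}'", hole))
  cmd <- m[2]
  if (!cmd %in% GA_TEMPLATE_COMMANDS)
    ga_stop("TEMPLATE_UNKNOWN_COMMAND",
            sprintf("unknown command '%s' in hole '${%s}'", cmd, hole))
  args <- trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
  args <- args[nzchar(args)]
  n_ok <- if (identical(cmd, "csv")) 2:3 else 1L
  if (!length(args) %in% n_ok)
    ga_stop("TEMPLATE_BAD_ARGS",
            sprintf("command '%s' takes %s argument(s), got %d in '${%s}'",
                    cmd, paste(n_ok, collapse = " or "), length(args), hole))
  list(cmd = cmd, args = args)
}

#' Render a template against a model element
#'
#' @param template a [ga_template()]
#' @param element a [ga_model()] (scope `model`) or [ga_entity()]
#'   (scope `per_entity`)
#' @param model the containing model; required so `sql_type` can resolve
#'   xref targets (defaults to `element` when that is a model)
#' @return the rendered text
#' @export
render <- function(template, element, model = NULL) {
  if (is.null(model) && inherits(element, "ga_model")) model <- element
  body <- template$body
  holes <- find_holes(body)
  for (h in holes) {
    value <- eval_hole(parse_hole(h), element, model)
    body <- sub(paste0("${", h, "}"), value, body, fixed = TRUE)
  }
  body
}

eval_hole <- function(hole, element, model) {
  cmd <- hole$cmd; args <- hole$args
  if (identical(cmd, "csv")) {
    sep <- if (length(args) >= 3) args[3] else ","
    items <- resolve_list(args[1], element, model)
    return(paste(vapply(items, apply_command, "", cmd = args[2],
                        model = model), collapse = sep))
  }
  target <- resolve_ref(args[1], element, model)
  apply_command(target, cmd, model)
}

resolve_ref <- function(ref, element, model) {
  if (identical(ref, "model")) {
    if (is.null(model)) ga_stop("TEMPLATE_BAD_ARGS", "no model in scope")
    return(model)
  }
  if (identical(ref, "entity")) {
    if (!inherits(element, "ga_entity"))
      ga_stop("TEMPLATE_BAD_ARGS",
              "'entity' is only available in per-entity templates")
    return(element)
  }
  ga_stop("TEMPLATE_BAD_ARGS", sprintf("unknown reference '%s'", ref))
}

resolve_list <- function(ref, element, model) {
  if (identical(ref, "entity.fields"))
    return(resolve_ref("entity", element, model)$fields)
  if (identical(ref, "model.entities"))
    return(resolve_ref("model", element, model)$entities)
  ga_stop("TEMPLATE_BAD_ARGS", sprintf("unknown list reference '%s'", ref))
}

apply_command <- function(x, cmd, model) {
  switch(cmd,
    Name = x$name,
    name = tolower(x$name),
    label = if (!is.null(x$label) && !is.na(x$label)) x$label else x$name,
    type = {
      if (!inherits(x, "ga_field"))
        ga_stop("TEMPLATE_BAD_ARGS", "'type' applies to fields only")
      x$type
    },
    sql_type = {
      if (!inherits(x, "ga_field"))
        ga_stop("TEMPLATE_BAD_ARGS", "'sql_type' applies to fields only")
      sql_type(x, model)
    },
    ga_stop("TEMPLATE_UNKNOWN_COMMAND", sprintf("unknown command '%s'", cmd)))
}
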