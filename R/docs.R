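#' Human-readable model documentation
#'
#' Renders one markdown section per entity: label, description, a field
#' table (name, type, nillable, readonly, unique, xref target) and an
#' inheritance note. Useful while a team is still designing and
#' discussing the model.
#'
#' @param model a valid, resolved [ga_model()]
#' @return markdown text
#' @export
model_docs <- function(model) {
  assert_valid(model)
  out <- c(sprintf("# Model: %s", model$name), "")
  for (e in model$entities) {
    out <- c(out, sprintf("## %s", e$label))
    if (!identical(e$label, e$name))
      out <- c(out, sprintf("(entity `%s`)", e$name))
    if (!is.na(e$extends))
      out <- c(out, sprintf("Extends `%s`; inherited fields are listed below.",
                            e$extends))
    if (!is.na(e$description)) out <- c(out, e$description)
    out <- c(out, "",
             "| field | type | nillable | readonly | unique | references |",
             "|---|---|---|---|---|---|")
    for (f in e$fields) {
      type <- if (identical(f$type, "string"))
        sprintf("string(%d)", f$max_length) else f$type
      ref <- if (identical(f$type, "xref"))
        sprintf("%s.%s", f$xref_entity, f$xref_field) else ""
      marker <- if (!is.na(f$inherited_from))
        sprintf(" *(from %s)*", f$inherited_from) else ""
      out <- c(out, sprintf("| %s%s | %s | %s | %s | %s | %s |",
                            f$name, marker, type,
                            tolower(f$nillable), tolower(f$readonly),
                            tolower(f$unique), ref))
    }
    out <- c(out, "")
  }
  paste(out, collapse = "\n")
}

#' Entity-relationship graph in DOT notation
#'
#' One record-shaped node per entity listing its fields, a solid directed
#' edge per cross-reference (source -> target, labeled with the field
#' name) and a dashed edge per inheritance link. The text renders with
#' graphviz and is also consumed as the machine-readable relationship
#' overview of the generated documentation.
#'
#' @param model a valid, resolved [ga_model()]
#' @return DOT graph text
#' @export
er_graph <- function(model) {
  assert_valid(model)
  lines <- c("digraph model {",
             "  rankdir=LR;",
             "  node [shape=record, fontsize=10];")
  for (e in model$entities) {
    fields <- vapply(e$fields, function(f) {
      paste0(f$name, ": ",
             if (identical(f$type, "string"))
               sprintf("string(%d)", f$max_length) else f$type)
    }, "")
    label <- paste0("{", e$name, "|", paste(fields, collapse = "\\l"), "\\l}")
    lines <- c(lines, sprintf("  %s [label=\"%s\"];", e$name, label))
  }
  for (e in model$entities) {
    for (f in xref_fields(e)) {
      lines <- c(lines, sprintf("  %s -> %s [label=\"%s\"];",
                                e$name, find_entity(model, f$xref_entity)$name,
                                f$name))
    }
    if (!is.na(e$extends))
      lines <- c(lines, sprintf("  %s -> %s [style=dashed, arrowhead=empty];",
                                e$name, find_entity(model, e$extends)$name))
  }
  paste(c(lines, "}"), collapse = "\n")
}
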