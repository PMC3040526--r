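#' Generate a complete application from a model
#'
#' Runs every generator over a validated model and writes the resulting
#' application directory: the relational schema (`schema.sql`), a
#' machine-readable ui layout (`ui/layout.json`), the REST route manifest
#' (`api/routes.json`), documentation (`docs/model.md`, `docs/model.dot`),
#' per-entity data-mapper descriptors (`mappers/*.txt`, rendered from the
#' template engine), an application config (`application.cfg`) and the
#' canonical model itself (`model.xml`).
#'
#' Generation is a pure function of the model: no timestamps unless
#' `stamp = TRUE`, byte-identical output on regeneration, and a manifest
#' (`.generated.json`) that lets the next run fully replace previously
#' generated files — improvements to the generators or the model
#' propagate by simply regenerating.
#'
#' @param model a valid, resolved [ga_model()]
#' @param out output directory (created if needed); `NULL` renders
#'   in-memory only
#' @param stamp add a generation timestamp comment to `application.cfg`
#' @return invisibly, a data frame of generated files: `path`, `content`,
#'   `template_id`, `model_locus`
#' @export
generate_application <- function(model, out = NULL, stamp = FALSE) {
  assert_valid(model, code = "GENERATE_INVALID_MODEL")
  files <- list()
  emit <- function(path, content, template_id, locus) {
    if (path %in% vapply(files, `[[`, "", "path"))
      ga_stop("GENERATE_PATH_CLASH",
              sprintf("two generators produced '%s'", path))
    files[[length(files) + 1L]] <<- list(path = path, content = content,
                                         template_id = template_id,
                                         model_locus = locus)
  }

  emit("schema.sql", paste0(schema_ddl(model), "\n"), "schema", "model")
  emit("docs/model.md", model_docs(model), "docs", "model")
  emit("docs/model.dot", paste0(er_graph(model), "\n"), "er_graph", "model")
  emit("api/routes.json",
       paste0(jsonlite::toJSON(rest_routes(model), dataframe = "rows",
                               pretty = TRUE), "\n"),
       "routes", "model")
  emit("ui/layout.json",
       paste0(jsonlite::toJSON(ui_layout(model), auto_unbox = TRUE,
                               pretty = TRUE, null = "null"), "\n"),
       "ui_layout", "model")
  emit("model.xml", serialize_model(model), "model_xml", "model")

  cfg <- render(builtin_template("application.cfg"), model)
  if (stamp)
    cfg <- paste0(cfg, "# generated at ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  "\n")
  emit("application.cfg", cfg, "application.cfg", "model")

  mapper <- builtin_template("mapper.txt")
  for (e in model$entities) {
    path <- sub("${Name}", e$name, mapper$output_path_pattern, fixed = TRUE)
    emit(path, render(mapper, e, model), mapper$id, e$name)
  }

  result <- do.call(rbind, lapply(files, function(f)
    data.frame(path = f$path, content = f$content,
               template_id = f$template_id, model_locus = f$model_locus,
               stringsAsFactors = FALSE)))
  if (!is.null(out)) write_generated(result, out)
  invisible(result)
}

# built-in generator templates shipped under inst/templates/
builtin_template <- function(id) {
  registry <- list(
    "application.cfg" = list(scope = "model", out = "application.cfg"),
    "mapper.txt" = list(scope = "per_entity", out = "mappers/${Name}.txt"))
  meta <- registry[[id]]
  if (is.null(meta))
    ga_stop("TEMPLATE_UNKNOWN", sprintf("no built-in template '%s'", id))
  path <- system.file("templates", paste0(id, ".tmpl"), package = "genapp",
                      mustWork = TRUE)
  read_template(path, scope = meta$scope, output_path_pattern = meta$out)
}

write_generated <- function(files, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out, ".generated.json")
  if (file.exists(manifest_path)) {
    old <- jsonlite::fromJSON(manifest_path)
    unlink(file.path(out, old))
  }
  for (i in seq_len(nrow(files))) {
    dest <- file.path(out, files$path[i])
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    writeLines(files$content[i], dest, sep = "")
  }
  jsonlite::write_json(files$path, manifest_path)
  invisible(out)
}

# declarative screen structure: forms with their resolved parent links
ui_layout <- function(model) {
  walk <- function(elements, parent_entity) {
    lapply(elements, function(el) {
      node <- list(kind = el$kind, name = el$name)
      if (identical(el$kind, "form")) {
        node$entity <- el$entity
        node$view <- el$view_mode
        if (!is.na(parent_entity)) {
          link <- resolve_form_link(model, find_entity(model, el$entity),
                                    parent_entity, el$link_field)
          node$link_field <- link$field
        }
        node$children <- walk(el$children, el$entity)
      } else if (identical(el$kind, "plugin")) {
        node$plugin_id <- el$plugin_id
        node$mount <- paste0("/api/v1/_plugin/", el$plugin_id)
      } else {
        node$children <- walk(el$children, parent_entity)
      }
      node
    })
  }
  list(application = model$name, screens = walk(model$ui, NA_character_))
}
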