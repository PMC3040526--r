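#' @title Synthetic models and data
#'
#' @description
#' Every module of the package is testable without external inputs:
#' [random_model()] draws structurally valid models (entities, typed
#' fields, acyclic cross-references, inheritance, a skeleton ui) from a
#' seeded generator, [random_data()] draws conforming tabular data for
#' any such model, and targeted defects can be injected for negative
#' tests. Names come from a molecular-genetics vocabulary so fixtures
#' read like the experiment databases the toolkit is meant for; value
#' distributions are deliberately simple (this emulates structure, not
#' biology).
#'
#' @name fixtures
NULL

GA_NAME_POOL <- c(
  "experiment", "sample", "hybridization", "marker", "trait", "subject",
  "assay", "protocol", "panel", "strain", "probe", "phenotype", "genotype",
  "cohort", "tissue", "extract", "array_design", "measurement", "locus",
  "investigation")

GA_FIELD_POOL <- c(
  "name", "description_text", "value", "score", "position", "chromosome",
  "medium", "stress", "batch", "operator_name", "quality", "status",
  "collected_on", "volume", "concentration", "passed_qc", "label_dye",
  "replicate", "source_well", "comment_text")

#' Specify a fixture model
#'
#' @param seed RNG seed; the same spec always yields the same model
#' @param n_entities number of entities
#' @param max_fields maximum non-key fields per entity
#' @param xref_density probability that an eligible entity gains a
#'   cross-reference to an earlier entity
#' @param inherit_probability probability that an entity extends an
#'   earlier one
#' @param defect `NULL` for a valid model, or one of `xref_missing`,
#'   `cycle`, `dup_field` (injected model defects) / `bad_header`
#'   (consumed by [random_data()])
#' @return a `ga_fixture_spec`
#' @export
fixture_spec <- function(seed = 1L, n_entities = 4L, max_fields = 5L,
                         xref_density = 0.6, inherit_probability = 0.2,
                         defect = NULL) {
  stopifnot(n_entities >= 1, max_fields >= 1,
            xref_density >= 0, xref_density <= 1,
            inherit_probability >= 0, inherit_probability <= 1)
  if (!is.null(defect))
    defect <- match.arg(defect,
                        c("xref_missing", "cycle", "dup_field", "bad_header"))
  structure(list(seed = as.integer(seed), n_entities = as.integer(n_entities),
                 max_fields = as.integer(max_fields),
                 xref_density = xref_density,
                 inherit_probability = inherit_probability, defect = defect),
            class = "ga_fixture_spec")
}

# run code under a local seeded RNG without disturbing the global stream
with_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Draw a random valid model
#'
#' Without an injected defect the result always passes [validate_model()]
#' with zero errors: every entity carries a non-nillable unique `id` key,
#' cross-references only target earlier-declared entities (hence acyclic)
#' and inheritance parents are earlier entities with disjoint field
#' names.
#'
#' @param spec a [fixture_spec()]
#' @return a resolved `ga_model`
#' @export
random_model <- function(spec = fixture_spec()) {
  with_rng(spec$seed, {
    n <- spec$n_entities
    enames <- unique_names(GA_NAME_POOL, n, suffix = TRUE)
    entities <- list()
    eff_names <- list()  # flattened (inheritance-inclusive) field names
    for (i in seq_len(n)) {
      fields <- list(ga_field("id", unique = TRUE, readonly = TRUE))
      nf <- sample.int(spec$max_fields, 1L)
      fnames <- unique_names(GA_FIELD_POOL, nf, suffix = TRUE)
      for (fn in fnames) {
        type <- sample(c("string", "text", "int", "decimal", "bool", "date"),
                       1L, prob = c(.35, .1, .2, .15, .1, .1))
        fields[[length(fields) + 1L]] <- ga_field(
          fn, type = type,
          nillable = stats::runif(1) < 0.4,
          max_length = if (identical(type, "string") && stats::runif(1) < 0.3)
            sample(c(20L, 50L, 100L), 1L) else NA_integer_)
      }
      extends <- NA_character_
      if (i > 1 && stats::runif(1) < spec$inherit_probability) {
        # parent must not share non-key field names; keys clash by design,
        # so the child drops its own key and inherits the parent's
        parent <- sample(i - 1L, 1L)
        extends <- enames[parent]
        fields <- fields[-1]
        fields <- Filter(function(f) !tolower(f$name) %in% eff_names[[parent]],
                         fields)
      }
      if (i > 1 && stats::runif(1) < spec$xref_density) {
        target <- sample(i - 1L, 1L)
        ref_name <- paste0(enames[target], "_ref")
        taken <- c(tolower(vapply(fields, `[[`, "", "name")),
                   if (!is.na(extends))
                     eff_names[[match(extends, enames)]])
        if (tolower(ref_name) %in% taken)
          ref_name <- paste0(ref_name, "_", i)
        fields[[length(fields) + 1L]] <- ga_field(
          ref_name, type = "xref",
          nillable = stats::runif(1) < 0.3,
          xref_entity = enames[target], xref_field = "id")
      }
      entities[[i]] <- ga_entity(enames[i], extends = extends,
                                 fields = fields)
      eff_names[[i]] <- c(
        if (!is.na(extends)) eff_names[[match(extends, enames)]],
        tolower(vapply(fields, `[[`, "", "name")))
    }
    ui <- list(ga_ui("plugin", "header", plugin_id = "app.header"))
    forms <- lapply(entities, function(e)
      ga_ui("form", paste0(e$name, "_form"), entity = e$name,
            view_mode = sample(c("record", "list"), 1L)))
    ui <- c(ui, list(ga_ui("menu", "main", children = forms)))
    model <- ga_model(paste0("fixture_", spec$seed), entities = entities,
                      ui = ui)
    model <- inject_defect(model, spec$defect)
    resolve_inheritance(apply_defaults(model))
  })
}

unique_names <- function(pool, n, suffix = FALSE) {
  base <- sample(pool, min(n, length(pool)))
  if (n > length(pool))
    base <- c(base, paste0(sample(pool, n - length(pool), replace = TRUE),
                           "_", seq_len(n - length(pool))))
  base
}

inject_defect <- function(model, defect) {
  if (is.null(defect) || identical(defect, "bad_header")) return(model)
  if (identical(defect, "xref_missing")) {
    e <- model$entities[[length(model$entities)]]
    e$fields[[length(e$fields) + 1L]] <- ga_field(
      "dangling_ref", type = "xref", nillable = TRUE,
      xref_entity = "no_such_entity", xref_field = "id")
    model$entities[[length(model$entities)]] <- e
  } else if (identical(defect, "cycle")) {
    if (length(model$entities) < 2)
      ga_stop("FIXTURE_BAD_SPEC", "cycle defect needs >= 2 entities")
    a <- model$entities[[1]]; b <- model$entities[[2]]
    a$fields[[length(a$fields) + 1L]] <- ga_field(
      "cycle_ref_fwd", type = "xref", xref_entity = b$name, xref_field = "id")
    b$fields[[length(b$fields) + 1L]] <- ga_field(
      "cycle_ref_back", type = "xref", xref_entity = a$name, xref_field = "id")
    model$entities[[1]] <- a; model$entities[[2]] <- b
  } else if (identical(defect, "dup_field")) {
    e <- model$entities[[1]]
    e$fields[[length(e$fields) + 1L]] <- ga_field(toupper(e$fields[[1]]$name))
    model$entities[[1]] <- e
  }
  model
}

#' Draw conforming data for a model
#'
#' Generates one tabular file per entity: unique keys, type-conforming
#' cells, cross-reference cells drawn from the generated target keys and
#' NULLs only in nillable fields. With the `bad_header` defect the first
#' entity's file gains a column naming no model field, for negative
#' import tests.
#'
#' @param model a valid, resolved [ga_model()]
#' @param rows_per_entity rows per file
#' @param seed RNG seed
#' @param defect `NULL` or `"bad_header"`
#' @return named list (entity name -> [ga_tabfile()])
#' @export
random_data <- function(model, rows_per_entity = 10L, seed = 1L,
                        defect = NULL) {
  assert_valid(model)
  with_rng(seed, {
    n <- rows_per_entity
    keys <- list()  # entity -> generated key values (text)
    files <- list()
    for (nm in entity_load_order(model)) {
      e <- find_entity(model, nm)
      kf <- key_field(e)
      cols <- list()
      kprefix <- toupper(substr(e$name, 1, 1))
      keyvals <- if (n == 0) character(0)
      else if (identical(effective_type(kf, model), "int"))
        as.character(seq_len(n))
      else paste0(kprefix, seq_len(n))
      for (f in e$fields) {
        cols[[f$name]] <- if (identical(f$name, kf$name)) keyvals
        else vapply(seq_len(n), function(i)
          random_cell(f, model, keys), "")
      }
      rows <- as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
      if (n == 0)
        rows <- as.data.frame(stats::setNames(
          replicate(length(e$fields), character(0), simplify = FALSE),
          field_names(e)), stringsAsFactors = FALSE, optional = TRUE)
      keys[[tolower(e$name)]] <- keyvals
      files[[e$name]] <- ga_tabfile(e$name, field_names(e), rows)
    }
    if (identical(defect, "bad_header") && length(files) > 0) {
      f <- files[[1]]
      f$rows$no_such_field <- rep("x", nrow(f$rows))
      f$header <- c(f$header, "no_such_field")
      files[[1]] <- f
    }
    # restore model declaration order for the returned list
    files[entity_names(model)[entity_names(model) %in% names(files)]]
  })
}

random_cell <- function(f, model, keys) {
  if (isTRUE(f$nillable) && stats::runif(1) < 0.15) return("")
  if (identical(f$type, "xref")) {
    pool <- keys[[tolower(f$xref_entity)]]
    if (is.null(pool) || length(pool) == 0)
      return("")  # soft edge with no target rows yet
    return(sample(pool, 1L))
  }
  switch(f$type,
    string = paste0(sample(letters, min(8L, f$max_length), replace = TRUE),
                    collapse = ""),
    text = paste(sample(c("lorem", "ipsum", "assay", "note"), 3L,
                        replace = TRUE), collapse = " "),
    int = as.character(sample.int(1000L, 1L)),
    decimal = format(round(stats::runif(1, 0, 100), 3), scientific = FALSE,
                     trim = TRUE),
    bool = sample(c("true", "false"), 1L),
    date = format(as.Date("2020-01-01") + sample.int(1000L, 1L), "%Y-%m-%d"),
    "")
}
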