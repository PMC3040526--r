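# shared fixtures and assertion helpers

# wrap entity/ui snippets into a resolved model
load_fixture_xml <- function(inner, name = "fixture") {
  load_model(sprintf("<molgenis name='%s'>%s</molgenis>", name, inner))
}

# a ga_field with conventions applied, for direct type-mapping checks
default_filled_field <- function(name, ...) {
  genapp:::default_fill_field(ga_field(name, ...))
}

# two entities referencing each other; the A->B edge is nillable (soft)
soft_cycle_model <- function() {
  load_fixture_xml('
    <entity name="A">
      <field name="id" unique="true"/>
      <field name="b" type="xref" xref_entity="B" xref_field="id" nillable="true"/>
    </entity>
    <entity name="B">
      <field name="id" unique="true"/>
      <field name="a" type="xref" xref_entity="A" xref_field="id"/>
    </entity>')
}

example_model_path <- function() {
  system.file("extdata", "microarray_model.xml", package = "genapp")
}

example_model <- function() load_model(example_model_path())

# expect that `expr` signals a genapp error carrying `code`
expect_ga_error <- function(expr, code) {
  cond <- tryCatch({ expr; NULL }, genapp_error = function(e) e)
  testthat::expect_false(is.null(cond),
                         label = sprintf("expected error with code %s", code))
  if (!is.null(cond)) testthat::expect_identical(error_code(cond), code)
  invisible(cond)
}

# a small hand-built model: B references A, C references B (load chain)
chain_model <- function() {
  m <- ga_model("chain", entities = list(
    ga_entity("A", fields = list(ga_field("id", unique = TRUE))),
    ga_entity("B", fields = list(
      ga_field("id", unique = TRUE),
      ga_field("a", type = "xref", xref_entity = "A", xref_field = "id"))),
    ga_entity("C", fields = list(
      ga_field("id", unique = TRUE),
      ga_field("b", type = "xref", xref_entity = "B", xref_field = "id")))))
  resolve_inheritance(apply_defaults(m))
}

# open an in-memory store populated with a couple of experiment rows
example_store <- function() {
  store <- store_open(example_model())
  ga_add(store, "Experiment",
         list(ID = "E1", Title = "heat shock", Medium = "glucose",
              Stress = "42C"))
  ga_add(store, "Experiment",
         list(ID = "E2", Title = "osmotic", Medium = "lactose",
              Stress = "NaCl"))
  ga_add(store, "Sample",
         list(ID = "S1", Experiment = "E1", Material = "culture"))
  store
}

# brute-force load-order oracle: all permutations satisfying every
# precedence constraint, as lists of entity-name vectors
oracle_load_orders <- function(model) {
  nms <- entity_names(model)
  n <- length(nms)
  stopifnot(n <= 7)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  constraints <- list()
  for (e in model$entities) {
    for (f in xref_fields(e)) {
      if (tolower(f$xref_entity) == tolower(e$name)) next
      constraints[[length(constraints) + 1L]] <-
        c(f$xref_entity, e$name)  # target before source
    }
  }
  Filter(function(p) {
    all(vapply(constraints, function(cn) {
      match(tolower(cn[1]), tolower(p)) < match(tolower(cn[2]), tolower(p))
    }, NA))
  }, perms(nms))
}
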