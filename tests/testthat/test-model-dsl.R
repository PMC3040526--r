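test_that("parsing the microarray example model yields the declared structure", {
  m <- parse_model(example_model_path())
  expect_s3_class(m, "ga_model")
  expect_length(m$entities, 3)
  nms <- vapply(m$entities, `[[`, "", "name")
  expect_identical(nms, c("Experiment", "Sample", "Hybridization"))
  exp <- m$entities[[1]]
  expect_length(exp$fields, 6)
  fn <- vapply(exp$fields, `[[`, "", "name")
  expect_true(all(c("ID", "Medium", "Stress") %in% fn))
  # raw parse keeps unset attributes unset
  medium <- exp$fields[[which(fn == "Medium")]]
  expect_true(is.na(medium$type))
  expect_true(is.na(medium$max_length))
})

test_that("empty documents, malformed XML and unknown markup are handled", {
  m <- parse_model("<molgenis name='empty'/>")
  expect_length(m$entities, 0)
  expect_identical(nrow(validate_model(resolve_inheritance(apply_defaults(m)))), 0L)

  expect_ga_error(parse_model("<molgenis><entity name='A'"),
                  "MODEL_PARSE_ERROR")
  expect_ga_error(parse_model("<molgenis><banana/></molgenis>"),
                  "MODEL_UNKNOWN_MARKUP")
  expect_warning(parse_model("<molgenis><banana/></molgenis>", strict = FALSE),
                 "unknown element")
  expect_ga_error(
    parse_model("<molgenis><entity name='A' colour='red'/></molgenis>"),
    "MODEL_UNKNOWN_MARKUP")
})

test_that("an xref typo parses but is caught by validation", {
  xml <- '<molgenis name="m">
    <entity name="Experiment"><field name="ID" unique="true"/></entity>
    <entity name="Sample">
      <field name="ID" unique="true"/>
      <field name="Experiment" type="xref" xref_entity="Experimnt" xref_field="ID"/>
    </entity></molgenis>'
  m <- resolve_inheritance(apply_defaults(parse_model(xml)))
  iss <- validate_model(m)
  expect_true("XREF_TARGET_MISSING" %in% iss$code)
})

test_that("conventions fill unset attributes and never touch set ones", {
  m <- apply_defaults(parse_model(
    '<molgenis name="m"><entity name="E">
       <field name="Medium"/>
       <field name="Size" type="int" nillable="true"/>
       <field name="Code" length="50"/>
     </entity></molgenis>'))
  f <- m$entities[[1]]$fields
  expect_identical(f[[1]]$type, "string")
  expect_identical(f[[1]]$max_length, 255L)
  expect_false(f[[1]]$nillable)
  expect_false(f[[1]]$readonly)
  expect_false(f[[1]]$unique)
  # explicit values survive
  expect_identical(f[[2]]$type, "int")
  expect_true(f[[2]]$nillable)
  expect_identical(f[[3]]$max_length, 50L)
  expect_identical(m$entities[[1]]$label, "E")
})

test_that("apply_defaults is idempotent on random models", {
  for (seed in c(1, 7, 23)) {
    raw <- parse_model(serialize_model(random_model(fixture_spec(seed = seed))))
    once <- apply_defaults(raw)
    expect_identical(apply_defaults(once), once)
  }
})

test_that("inheritance flattens ancestor-first and rejects cycles", {
  m <- apply_defaults(parse_model(
    '<molgenis name="m">
       <entity name="A"><field name="id" unique="true"/></entity>
       <entity name="B" extends="A"><field name="x"/></entity>
       <entity name="C" extends="B"><field name="y"/></entity>
     </molgenis>'))
  r <- resolve_inheritance(m)
  expect_identical(vapply(r$entities[[2]]$fields, `[[`, "", "name"),
                   c("id", "x"))
  # oracle: flatten by repeated parent lookup
  oracle_flatten <- function(model, name) {
    e <- find_entity(model, name)
    if (is.na(e$extends)) return(vapply(e$fields, `[[`, "", "name"))
    c(oracle_flatten(model, e$extends), vapply(e$fields, `[[`, "", "name"))
  }
  expect_identical(vapply(r$entities[[3]]$fields, `[[`, "", "name"),
                   oracle_flatten(m, "C"))
  expect_length(r$entities[[3]]$fields, 3)

  cyc <- apply_defaults(parse_model(
    '<molgenis name="m">
       <entity name="A" extends="B"><field name="a" unique="true"/></entity>
       <entity name="B" extends="A"><field name="b" unique="true"/></entity>
     </molgenis>'))
  expect_ga_error(resolve_inheritance(cyc), "MODEL_INHERITANCE_CYCLE")

  dup <- apply_defaults(parse_model(
    '<molgenis name="m">
       <entity name="A"><field name="id" unique="true"/></entity>
       <entity name="B" extends="A"><field name="ID"/></entity>
     </molgenis>'))
  expect_ga_error(resolve_inheritance(dup), "FIELD_REDECLARED")
})

test_that("validation accepts the example model and flags broken invariants", {
  expect_identical(nrow(validate_model(example_model())), 0L)

  bad <- load_fixture_xml('
    <entity name="A">
      <field name="id" unique="true"/>
      <field name="tag"/>
    </entity>
    <entity name="B">
      <field name="id" unique="true"/>
      <field name="a" type="xref" xref_entity="A" xref_field="tag"/>
    </entity>')
  expect_true("XREF_TARGET_NOT_UNIQUE" %in% validate_model(bad)$code)

  # two xrefs to the parent entity and no explicit link
  amb <- load_fixture_xml('
    <entity name="P"><field name="id" unique="true"/></entity>
    <entity name="CH">
      <field name="id" unique="true"/>
      <field name="p1" type="xref" xref_entity="P" xref_field="id"/>
      <field name="p2" type="xref" xref_entity="P" xref_field="id"/>
    </entity>
    <ui><form name="parent" entity="P">
      <form name="child" entity="CH" view="list"/>
    </form></ui>')
  expect_true("UI_AMBIGUOUS_LINK" %in% validate_model(amb)$code)
  # the same structure with an explicit link field is clean
  ok <- load_fixture_xml('
    <entity name="P"><field name="id" unique="true"/></entity>
    <entity name="CH">
      <field name="id" unique="true"/>
      <field name="p1" type="xref" xref_entity="P" xref_field="id"/>
      <field name="p2" type="xref" xref_entity="P" xref_field="id"/>
    </entity>
    <ui><form name="parent" entity="P">
      <form name="child" entity="CH" view="list" link_field="p1"/>
    </form></ui>')
  expect_identical(nrow(validate_model(ok)), 0L)

  noref <- load_fixture_xml('
    <entity name="P"><field name="id" unique="true"/></entity>
    <entity name="Q"><field name="id" unique="true"/></entity>
    <ui><form name="parent" entity="P">
      <form name="child" entity="Q" view="list"/>
    </form></ui>')
  expect_true("UI_NO_LINK" %in% validate_model(noref)$code)
})

test_that("load order places referenced entities first, deterministically", {
  m <- example_model()
  ord <- entity_load_order(m)
  expect_lt(match("Experiment", ord), match("Sample", ord))
  expect_lt(match("Sample", ord), match("Hybridization", ord))

  # chain C -> B -> A in reverse declaration order
  chain <- load_fixture_xml('
    <entity name="C">
      <field name="id" unique="true"/>
      <field name="b" type="xref" xref_entity="B" xref_field="id"/>
    </entity>
    <entity name="B">
      <field name="id" unique="true"/>
      <field name="a" type="xref" xref_entity="A" xref_field="id"/>
    </entity>
    <entity name="A"><field name="id" unique="true"/></entity>')
  expect_identical(entity_load_order(chain), c("A", "B", "C"))

  # hard two-entity cycle is rejected
  cyc <- load_fixture_xml('
    <entity name="A">
      <field name="id" unique="true"/>
      <field name="b" type="xref" xref_entity="B" xref_field="id"/>
    </entity>
    <entity name="B">
      <field name="id" unique="true"/>
      <field name="a" type="xref" xref_entity="A" xref_field="id"/>
    </entity>')
  expect_ga_error(entity_load_order(cyc), "MODEL_XREF_CYCLE")
  expect_true("MODEL_XREF_CYCLE" %in% validate_model(cyc)$code)

  # a nillable edge softens the cycle and is relaxed in the order
  soft <- soft_cycle_model()
  expect_identical(nrow(validate_model(soft)), 0L)
  expect_identical(entity_load_order(soft), c("A", "B"))
})

test_that("load order matches the brute-force permutation oracle", {
  for (seed in c(2, 5, 11, 17)) {
    m <- random_model(fixture_spec(seed = seed,
                                   n_entities = sample(3:6, 1)))
    valid <- oracle_load_orders(m)
    ord <- entity_load_order(m)
    expect_true(any(vapply(valid, identical, NA, y = ord)),
                label = sprintf("seed %d order among valid permutations", seed))
    # tie-break minimality: first valid permutation in declaration-index
    # lexicographic order
    idx <- function(p) match(tolower(p), tolower(entity_names(m)))
    best <- valid[[which.min(vapply(valid, function(p)
      sum(idx(p) * (length(p) + 1)^rev(seq_along(p))), 0))]]
    expect_identical(ord, best)
  }
})

test_that("serialization round-trips and omits convention defaults", {
  m <- example_model()
  expect_true(model_equal(m, load_model(serialize_model(m))))

  xml <- serialize_model(apply_defaults(parse_model(
    '<molgenis name="m"><entity name="E"><field name="plain"/></entity></molgenis>')))
  doc <- xml2::read_xml(xml)
  field <- xml2::xml_find_first(doc, "//field")
  expect_identical(names(xml2::xml_attrs(field)), "name")

  for (seed in 1:10) {
    rm <- random_model(fixture_spec(seed = seed))
    expect_true(model_equal(rm, load_model(serialize_model(rm))),
                label = sprintf("round-trip seed %d", seed))
  }
})
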