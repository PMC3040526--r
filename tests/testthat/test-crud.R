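test_that("add persists records and enforces model rules", {
  s <- store_open(example_model())
  on.exit(store_close(s))
  rec <- ga_add(s, "Experiment",
                list(ID = "E1", Title = "t", Medium = "glucose",
                     Stress = "42C"))
  expect_identical(rec$ID, "E1")
  expect_identical(ga_count(s, "Experiment"), 1L)

  expect_ga_error(
    ga_add(s, "Experiment", list(Title = "x", Medium = "m", Stress = "s")),
    "NOT_NILLABLE")
  expect_ga_error(
    ga_add(s, "Sample", list(ID = "S1", Experiment = "E9", Material = "x")),
    "XREF_UNRESOLVED")
  expect_ga_error(
    ga_add(s, "Experiment",
           list(ID = "E1", Title = "t", Medium = "m", Stress = "s")),
    "DUPLICATE_KEY")
  expect_ga_error(
    ga_add(s, "Experiment", list(ID = "E2", Banana = "x")),
    "QUERY_UNKNOWN_FIELD")
  expect_identical(ga_count(s, "Experiment"), 1L)
})

test_that("find filters conjunctively, pages and sorts deterministically", {
  s <- example_store()
  on.exit(store_close(s))
  res <- ga_find(s, "Experiment",
                 filters = list(flt("Medium", "equals", "glucose")))
  expect_identical(res$total, 1L)
  expect_identical(res$records$ID, "E1")

  all <- ga_find(s, "Experiment")
  expect_identical(all$total, 2L)
  expect_identical(nrow(all$records), 2L)

  page1 <- ga_find(s, "Experiment", page = pg(0, 1))
  expect_identical(nrow(page1$records), 1L)
  expect_identical(page1$total, 2L)   # total ignores the page

  desc_sort <- ga_find(s, "Experiment", sort = "Title")
  expect_identical(desc_sort$records$Title, sort(desc_sort$records$Title))

  expect_ga_error(ga_find(s, "Experiment",
                          filters = list(flt("Nope", "equals", 1))),
                  "QUERY_UNKNOWN_FIELD")
  expect_ga_error(ga_find(s, "Experiment",
                          filters = list(flt("ExperimentDate", "like", "x"))),
                  "QUERY_BAD_OP")
  expect_ga_error(pg(-1, 10), "QUERY_BAD_PAGE")
  expect_ga_error(pg(0, 100000), "QUERY_BAD_PAGE")
})

test_that("count equals the length of the unpaged find", {
  m <- random_model(fixture_spec(seed = 12, n_entities = 3))
  s <- store_open(m)
  on.exit(store_close(s))
  import_batch(s, random_data(m, rows_per_entity = 20, seed = 12))
  for (e in m$entities) {
    expect_identical(ga_count(s, e$name),
                     nrow(ga_find(s, e$name)$records))
  }
})

test_that("range filters agree with a linear scan of the exported file", {
  m <- load_fixture_xml('
    <entity name="Measure">
      <field name="id" unique="true"/>
      <field name="value" type="decimal"/>
    </entity>')
  s <- store_open(m)
  on.exit(store_close(s))
  set.seed(42)
  vals <- round(stats::runif(50, 0, 10), 3)
  for (i in seq_along(vals))
    ga_add(s, "Measure", list(id = paste0("M", i), value = vals[i]))
  cut <- 5
  res <- ga_find(s, "Measure", filters = list(flt("value", "lt", cut)))
  # oracle: brute-force scan over the exported table
  tab <- export_entity(s, "Measure")
  scan <- tab$rows$id[as.numeric(tab$rows$value) < cut]
  expect_setequal(res$records$id, scan)
  expect_identical(res$total, length(scan))
  # like on the string key
  like <- ga_find(s, "Measure", filters = list(flt("id", "like", "M1%")))
  expect_setequal(like$records$id, tab$rows$id[startsWith(tab$rows$id, "M1")])
})

test_that("update honors read-only fields and remove honors references", {
  s <- example_store()
  on.exit(store_close(s))
  up <- ga_update(s, "Experiment", "E2", list(Title = "osmotic shock"))
  expect_identical(up$Title, "osmotic shock")
  # the key is declared readonly in the model
  expect_ga_error(ga_update(s, "Experiment", "E2", list(ID = "EX")),
                  "READONLY_VIOLATION")
  expect_ga_error(ga_update(s, "Experiment", "E9", list(Title = "x")),
                  "NOT_FOUND")
  expect_ga_error(ga_update(s, "Experiment", "E2", list(Title = NA)),
                  "NOT_NILLABLE")

  expect_ga_error(ga_remove(s, "Experiment", "E1"), "REFERENTIAL_BLOCK")
  expect_identical(ga_remove(s, "Sample", "S1"), 1L)
  expect_identical(ga_remove(s, "Experiment", "E1"), 1L)
  expect_identical(ga_find(s, "Experiment")$total, 1L)
  expect_ga_error(ga_remove(s, "Experiment", "E1"), "NOT_FOUND")
})

test_that("record navigation is plain offset arithmetic", {
  nav <- page_nav(total = 5, offset = 2)
  expect_identical(nav$first, 0L)
  expect_identical(nav$previous, 1L)
  expect_identical(nav$`next`, 3L)
  expect_identical(nav$last, 4L)
  edge <- page_nav(total = 0, offset = 0)
  expect_identical(edge$`next`, 0L)
  expect_identical(edge$last, 0L)
})

test_that("typed columns round-trip through the store", {
  m <- load_fixture_xml('
    <entity name="T">
      <field name="id" unique="true"/>
      <field name="n" type="int"/>
      <field name="x" type="decimal"/>
      <field name="ok" type="bool"/>
      <field name="day" type="date" nillable="true"/>
    </entity>')
  s <- store_open(m)
  on.exit(store_close(s))
  ga_add(s, "T", list(id = "a", n = 3L, x = 2.5, ok = TRUE,
                      day = as.Date("2021-05-04")))
  rec <- ga_get(s, "T", "a")
  expect_identical(rec$n, 3L)
  expect_identical(rec$x, 2.5)
  expect_identical(rec$ok, TRUE)
  expect_identical(rec$day, as.Date("2021-05-04"))
})
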