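test_that("export writes all flattened fields, sorted by key, NULL as empty", {
  s <- example_store()
  on.exit(store_close(s))
  tab <- export_entity(s, "Experiment")
  expect_identical(tab$header,
                   c("ID", "Title", "Description", "Medium", "Stress",
                     "ExperimentDate"))
  expect_identical(nrow(tab$rows), 2L)
  expect_identical(tab$rows$ID, c("E1", "E2"))
  expect_identical(tab$rows$Description, c("", ""))  # NULL -> empty cell
  # the xref cell carries the referenced key value
  sm <- export_entity(s, "Sample")
  expect_identical(sm$rows$Experiment, "E1")
  # empty table -> header-only file
  hy <- export_entity(s, "Hybridization")
  expect_identical(nrow(hy$rows), 0L)
  expect_identical(hy$header, field_names(find_entity(s$model, "Hybridization")))
})

test_that("tsv files round-trip through disk including awkward cells", {
  rows <- data.frame(id = c("a", "b", "c"),
                     note = c("plain", "has\ttab", "has \"quotes\""),
                     empty = c("", "x", ""),
                     stringsAsFactors = FALSE)
  tab <- ga_tabfile("T", names(rows), rows)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tabfile(tab, path)
  back <- read_tabfile(path, entity = "T")
  expect_identical(back$rows, rows)
  # the literal string "null" stays literal text
  rows2 <- data.frame(id = "a", note = "null", stringsAsFactors = FALSE)
  write_tabfile(ga_tabfile("T", names(rows2), rows2), path)
  expect_identical(read_tabfile(path)$rows$note, "null")
})

test_that("import resolves xrefs, reports row errors, applies valid rows", {
  s <- example_store()
  on.exit(store_close(s))
  file <- ga_tabfile("Sample", c("ID", "Experiment", "Material"),
                     data.frame(ID = c("S2", "S3", "S4"),
                                Experiment = c("E1", "E9", "E2"),
                                Material = c("culture", "culture", ""),
                                stringsAsFactors = FALSE))
  rep <- import_file(s, "Sample", file)
  expect_identical(rep$rows_added, 1L)
  expect_identical(rep$rows_updated, 0L)
  expect_identical(nrow(rep$errors), 2L)
  expect_setequal(rep$errors$code, c("XREF_UNRESOLVED", "NOT_NILLABLE"))
  # conservation: added + updated + error rows = input rows
  expect_identical(rep$rows_added + rep$rows_updated + nrow(rep$errors), 3L)
  # the valid row was applied despite its bad neighbours (row-atomicity)
  expect_identical(ga_get(s, "Sample", "S2")$Experiment, "E1")
})

test_that("a header column matching no model field rejects the whole file", {
  s <- example_store()
  on.exit(store_close(s))
  file <- ga_tabfile("Sample", c("ID", "Experiment", "Mediums"),
                     data.frame(ID = "S9", Experiment = "E1", Mediums = "x",
                                stringsAsFactors = FALSE))
  expect_ga_error(import_file(s, "Sample", file), "IMPORT_UNKNOWN_COLUMN")
  expect_ga_error(ga_get(s, "Sample", "S9"), "NOT_FOUND")
})

test_that("duplicate keys within a file and mode semantics are honored", {
  s <- example_store()
  on.exit(store_close(s))
  file <- ga_tabfile("Experiment", c("ID", "Title", "Medium", "Stress"),
                     data.frame(ID = c("E5", "E5"), Title = c("a", "b"),
                                Medium = c("m", "m"), Stress = c("s", "s"),
                                stringsAsFactors = FALSE))
  rep <- import_file(s, "Experiment", file)
  expect_identical(rep$rows_added, 1L)
  expect_identical(rep$errors$code, "DUPLICATE_KEY")

  # add mode refuses existing keys; update mode refuses new keys
  f2 <- ga_tabfile("Experiment", c("ID", "Title", "Medium", "Stress"),
                   data.frame(ID = c("E5", "E6"), Title = c("c", "d"),
                              Medium = c("m", "m"), Stress = c("s", "s"),
                              stringsAsFactors = FALSE))
  rep_up <- import_file(s, "Experiment", f2, mode = "update")
  expect_identical(rep_up$rows_updated, 1L)
  expect_identical(ga_get(s, "Experiment", "E5")$Title, "c")
  expect_identical(rep_up$errors$code, "NOT_FOUND")
  rep_add <- import_file(s, "Experiment", f2, mode = "add")
  expect_identical(rep_add$rows_added, 1L)
  expect_identical(rep_add$errors$code, "DUPLICATE_KEY")

  # default add_update upserts
  rep_ud <- import_file(s, "Experiment", f2)
  expect_identical(rep_ud$rows_updated, 2L)
})

test_that("batch import follows load order and fills soft cycles in pass two", {
  s <- example_store()
  on.exit(store_close(s))
  files <- list(
    Sample = ga_tabfile("Sample", c("ID", "Experiment", "Material"),
                        data.frame(ID = "S7", Experiment = "E7",
                                   Material = "x", stringsAsFactors = FALSE)),
    Experiment = ga_tabfile("Experiment",
                            c("ID", "Title", "Medium", "Stress"),
                            data.frame(ID = "E7", Title = "t", Medium = "m",
                                       Stress = "s", stringsAsFactors = FALSE)))
  reps <- import_batch(s, files)   # Experiment must be imported first
  expect_identical(names(reps), c("Experiment", "Sample"))
  expect_identical(sum(vapply(reps, function(r) nrow(r$errors), 0L)), 0L)
  expect_identical(ga_get(s, "Sample", "S7")$Experiment, "E7")

  expect_ga_error(import_batch(s, list(Nope = files$Sample)),
                  "IMPORT_UNKNOWN_ENTITY")
})

test_that("mutually referencing rows across a nillable cycle import fully", {
  m <- soft_cycle_model()
  s <- store_open(m)
  on.exit(store_close(s))
  files <- list(
    A = ga_tabfile("A", c("id", "b"),
                   data.frame(id = "a1", b = "b1", stringsAsFactors = FALSE)),
    B = ga_tabfile("B", c("id", "a"),
                   data.frame(id = "b1", a = "a1", stringsAsFactors = FALSE)))
  reps <- import_batch(s, files)
  expect_identical(sum(vapply(reps, function(r) nrow(r$errors), 0L)), 0L)
  expect_identical(ga_get(s, "A", "a1")$b, "b1")   # filled in second pass
  expect_identical(ga_get(s, "B", "b1")$a, "a1")
})

test_that("export after import reproduces generated data", {
  for (seed in c(3, 9)) {
    m <- random_model(fixture_spec(seed = seed, n_entities = 4))
    s <- store_open(m)
    data <- random_data(m, rows_per_entity = 8, seed = seed)
    reps <- import_batch(s, data)
    expect_identical(sum(vapply(reps, function(r) nrow(r$errors), 0L)), 0L)
    for (nm in names(data)) {
      e <- find_entity(m, nm)
      back <- export_entity(s, nm)
      orig <- data[[nm]]$rows
      # canonical row order: sort by key
      orig <- orig[order(orig[[key_field(e)$name]]), , drop = FALSE]
      rownames(orig) <- NULL
      back_rows <- back$rows[order(back$rows[[key_field(e)$name]]), ,
                             drop = FALSE]
      rownames(back_rows) <- NULL
      expect_equal(back_rows, orig, ignore_attr = TRUE,
                   label = sprintf("seed %d entity %s", seed, nm))
    }
    store_close(s)
  }
})
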