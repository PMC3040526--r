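---
title: "Model-driven generation of data-management applications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-driven generation of data-management applications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genapp)
```

## The method

Biological data-management systems within one family (experiment
tracking, biobanking, genotype/phenotype stores) share almost all of
their machinery — storage, CRUD logic, file exchange, service
interfaces — and differ mainly in their *data structures* and *screen
structure*. `genapp` separates the two: the shared machinery is fixed,
reusable code in this package, and everything variable is declared in a
compact XML model. Generators then specialize the machinery per model.
Because the generators are shared by every application built this way,
a fix or improvement to a generator reaches each application by simply
regenerating it; this is the central maintenance argument for the
model-driven approach.

The package deliberately generates *declarative artifacts* (a DDL
script, JSON route and layout manifests, markdown/DOT documentation,
mapper descriptors) interpreted by the runtime modules, rather than
source code in a host language. The generator architecture is the same,
but every output is deterministic, diffable and byte-exactly testable.

## The modeling language

A model is one XML file with entities, typed fields and a ui tree.
Semantics worth spelling out:

* **Convention over configuration.** Unset attributes get fixed
  defaults: `type` = `string`, `max_length` = 255 characters,
  `nillable` = `false` (a value is required), `readonly` = `false`,
  `unique` = `false`, labels default to names, forms show one record
  per screen unless declared `view="list"`. `apply_defaults()` is
  idempotent and never overwrites an explicit attribute, and parsing is
  kept separate from default-filling so a serialized model is *canonical*:
  only deviations from convention are written.
* **Types.** `string`, `text`, `int`, `decimal`, `bool`, `date`,
  `xref`. A cross-reference must name an explicitly `unique` field of
  its target entity — there are no implicit surrogate keys, an entity's
  identity is its first unique field. References to reference fields
  (chains) are rejected, as are many-to-many references; both keep the
  relational mapping and the exchange format unambiguous.
* **Inheritance.** `extends` prepends the parent's flattened fields to
  the child's. Redeclaring an inherited field is an error rather than an
  override: silent shadowing is a classic source of schema drift.
* **Child-form linking.** A form nested in another form is linked
  through the single xref connecting their entities; two candidate
  xrefs make the model ambiguous and require an explicit `link_field`.
  Only direct (one-hop) links are supported — a multi-hop link cannot
  be expressed as one foreign-key filter and would make the layout
  descriptor ambiguous.
* **Reference cycles.** A cycle of non-nillable xrefs can never be
  loaded (no row of either entity could be inserted first) and is a
  validation error. A cycle containing a nillable edge is legal: the
  load order treats the nillable edge as *soft*, and the batch importer
  inserts those cells as NULL and fills them in a second pass. A
  self-reference must be nillable for the same reason.
* **Strictness.** Unknown elements or attributes are errors by default
  (`strict = TRUE`), warnings in lax mode — useful when reading models
  written for a newer vocabulary.

Validation returns a data frame of issues with stable machine codes
drawn from a closed enumeration (see `?validate_model`) rather than
failing on the first problem, so a model author sees every defect in
one pass. Everything downstream (`schema_ddl()`,
`generate_application()`, `store_open()`) refuses models with
validation errors.

## Load order

`entity_load_order()` topologically sorts entities so every referenced
entity precedes its referrers, with ties broken by declaration order
(Kahn's algorithm always taking the earliest-declared ready entity,
which yields the declaration-lexicographic minimum among all valid
orders — a deterministic choice that keeps regeneration byte-identical).
The test suite checks the order against a brute-force permutation
oracle for models of up to 7 entities, above which enumeration is no
longer practical.

## Schema generation and the embedded engine

The mapping is fixed and invertible: `string(n)` ⇄ `VARCHAR(n)`,
`text` ⇄ `TEXT`, `int` ⇄ `INTEGER`, `decimal` ⇄ `DOUBLE PRECISION`,
`bool` ⇄ `BOOLEAN`, `date` ⇄ `DATE`; an xref column takes the SQL type
of its target key. The single target dialect is SQLite (via RSQLite),
chosen because it is embedded, ubiquitous and enforces the three
constraint kinds the model declares; the mapping table is a plain named
vector, so a second dialect would be one more table rather than a
redesign. `readonly` is deliberately *not* a schema concern — it is an
application rule (a field fixed at creation time), enforced in the CRUD
layer where a meaningful error can be raised per request.

Constraint fidelity is tested behaviorally, not textually: tests insert
NULL into required columns, duplicate keys into unique columns and
dangling references into foreign-key columns and assert the engine
rejects each.

## Data exchange

The exchange dialect is UTF-8, tab-separated, header row first,
CSV-style double-quote escaping when a cell contains a tab, newline or
quote. An empty cell encodes NULL; the literal string `"null"` is just
text. These choices are local conventions (the format itself only fixes
"headers name model fields"), and they round-trip exactly.

Imports are *row-atomic rather than file-atomic*: every valid row is
applied and every invalid row is reported with its row number, field
and code. For batch loads of real lab data this surfaces all
inconsistencies in one pass instead of failing at the first one. The
report satisfies `rows_added + rows_updated + error rows = input rows`
by construction, and the default mode is an upsert keyed on the
entity's first unique field, which is what iterating on a spreadsheet
against a live store needs. A header column naming no model field
rejects the whole file — that situation almost always means the file
belongs to a different model version, and importing the remaining
columns would silently drop data.

## CRUD and REST

Filters are conjunctive only (`equals`, `like`, `lt`, `le`, `gt`,
`ge`); disjunction is out of scope, matching the simple filter screens
this family of systems offers. `like` applies to string/text fields
only, with `%`/`_` wildcards. Every query result is deterministically
ordered (requested sort field, then the key) so pagination is stable.
First/previous/next/last navigation is offset arithmetic
(`page_nav()`), not server-side cursor state. The REST layer is a pure
function from requests to responses (`handle_request()`); `serve()` is
a thin httpuv adapter over it, which is why the test suite can
exercise the full API contract without sockets. Declared ui plugins
surface as named extension points mounted under `/api/v1/_plugin/`;
the package ships the mechanism, not any plugin.

## Extraction

`extract_model()` inverts the schema mapping on an introspected
database or DDL script. The *lossy set* is documented and fixed: screen
structure, labels, descriptions, `readonly` flags and inheritance
structure (extraction sees only flattened tables) cannot be recovered.
Extraction degrades rather than fails: unmapped column types become
strings, foreign keys onto non-unique columns promote the target to
unique, composite foreign keys are dropped with their columns kept,
keyless tables get their first column promoted to key — each with a
warning issue. A skeleton ui (one list form per entity) is emitted so
the extracted application is immediately browsable. One genuine gap
remains: a database whose foreign keys form a cycle with no nullable
column cannot be expressed as a valid model and will fail validation
after extraction.

## The fixture generator

`random_model()` draws structurally valid models: 4 entities by
default, up to 5 non-key fields each with types drawn roughly in
proportion to their frequency in real experiment schemas
(strings dominating), a 0.6 chance of a cross-reference to an
earlier-declared entity (keeping the reference graph acyclic by
construction), a 0.2 chance of inheriting from an earlier entity, and
always a non-nillable unique `id` key. Names come from a
molecular-genetics vocabulary so fixtures read like the target domain.
`random_data()` draws type-conforming rows with unique keys, reference
cells drawn from generated target keys, and NULLs only in nillable
fields (15% of the time). Both are deterministic given their seed, with
the RNG state restored afterwards.

What the fixtures emulate is *structure* — entity graphs, constraint
combinations, reference topologies, header/row shapes. What they do not
emulate is the statistics of real biological values, multi-user
concurrency, or files that violate the dialect (encoding problems,
ragged rows). Passing the property suites therefore demonstrates
structural correctness of the pipeline, not robustness against every
real-world file.

Defect injection (`xref_missing`, `cycle`, `dup_field`, `bad_header`)
produces models and files that must fail with specific codes; the
validator's soundness property — any model whose generated DDL the
engine rejects was already flagged by `validate_model()` — is fuzzed
over these.

## Problem sizes and numerical choices

The test and acceptance suites use sizes chosen to exercise every code
path while staying quick to run: 100 seeded models for the
parse/serialize and extraction round-trips, 50 for schema execution,
models of 2–7 entities against the permutation oracle, 10–25 rows per
entity for exchange and query-oracle checks. Decimal cells are written
with `format(..., scientific = FALSE)` and compared textually after a
full store round-trip, which holds because both directions pass through
the same double-precision value; no tolerance is needed. Page limits
are capped at 1000 rows per request; identifier names are restricted to
`[A-Za-z][A-Za-z0-9_]*` so generated SQL and DOT never need quoting.

## Known limitations

Single inheritance only; no many-to-many references; no partial model
includes; no security layer (users, roles, privileges); no HTML GUI —
the ui tree is generated as a machine-readable layout descriptor plus
the REST service, not rendered screens; one SQL dialect; conjunctive
filters only. Within those bounds, the whole pipeline —
validate → generate → execute → import → export → extract — is checked
end-to-end for every fixture seed in the test suite.
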