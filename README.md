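# genapp — model-driven generation of biological data-management applications

Research groups producing *omics data need bespoke information systems —
one lab tracks experiments, samples and hybridizations, the next tracks
cohorts, markers and phenotypes — and hand-writing a database, user
interface, exchange format and API for each variant is slow and
error-prone. `genapp` takes the model-driven route: you describe your
experiment's data structures and screens in a compact XML modeling
language, and a generator suite turns that model into a working
data-management backend. When the science changes, you change the model
and regenerate.

From one model file you get:

- a **relational schema** (one table per entity, typed columns,
  `NOT NULL`/`UNIQUE`/`FOREIGN KEY` constraints) executed on an embedded
  SQLite engine;
- a **CRUD data layer and REST/JSON service** — add, update, remove,
  find and count any entity, with conjunctive filters, deterministic
  sorting and offset/limit pagination;
- a **tab-delimited import/export tool tailored to the model** — file
  headers must name model fields, cross-reference cells carry the
  referenced row's key, batch imports run in dependency order and every
  import yields a per-row report;
- **documentation** — a markdown data dictionary plus an
  entity-relationship graph in DOT notation;
- a **reverse-engineering path** (`extract_model()`) that recovers a
  model from an existing relational schema, so legacy databases gain all
  of the above without migration.

## The modeling language

A model declares *entities* with typed *fields* and a declarative *ui*
section. Convention over configuration keeps models short: a field is a
`string` of length 255, required, editable and non-unique unless declared
otherwise. Cross-references (`xref`) point at a unique field of another
entity and become foreign keys; entities can inherit fields with
`extends`; child forms are automatically linked to their parent form
through the connecting cross-reference.

```xml
<molgenis name="microarray">
  <entity name="Experiment">
    <field name="ID" unique="true" readonly="true"/>
    <field name="Medium"/>
    <field name="Stress"/>
    <field name="ExperimentDate" type="date" nillable="true"/>
  </entity>
  <entity name="Sample">
    <field name="ID" unique="true" readonly="true"/>
    <field name="Experiment" type="xref" xref_entity="Experiment" xref_field="ID"/>
  </entity>
  <ui>
    <form name="Experiments" entity="Experiment">
      <form name="Samples" entity="Sample" view="list"/>
    </form>
  </ui>
</molgenis>
```

## Worked example

The package ships a complete microarray model
(`inst/extdata/microarray_model.xml`) with entities Experiment, Sample
and Hybridization:

```r
library(genapp)

model <- load_model(system.file("extdata", "microarray_model.xml",
                                package = "genapp"))
model
#> <ga_model> microarray: 3 entities, 2 top-level ui elements
#>   Experiment (6 fields)
#>   Sample (4 fields)
#>   Hybridization (4 fields)

store <- store_open(model)            # executes the generated schema
ga_add(store, "Experiment",
       list(ID = "E1", Title = "heat shock", Medium = "glucose",
            Stress = "42C"))
ga_add(store, "Sample",
       list(ID = "S1", Experiment = "E1", Material = "culture"))

ga_find(store, "Sample", filters = list(flt("Experiment", "equals", "E1")))$records
#>   ID Experiment Material OD600
#> 1 S1         E1  culture    NA

app <- rest_app(store)
handle_request(app, "GET", "/api/v1/sample", query = list(Experiment = "E1"))$body
#> {"items":[{"ID":"S1","Experiment":"E1","Material":"culture","OD600":null}],
#>  "total":1,"offset":0,"limit":100}
```

The one-record `items` envelope is what every generated application
serves: the Sample row whose `Experiment` cross-reference resolves to
experiment `E1`, with its empty optical-density measurement encoded as
JSON `null`. `generate_application(model, out = "app/")` writes the full
artifact set (schema.sql, docs/, api/routes.json, ui/layout.json,
per-entity mapper descriptors) and is byte-identical on regeneration.

A thin command-line wrapper covers the same operations
(`generate`, `import`, `export`, `extract`, `fixtures`, `serve`):

```sh
Rscript $(Rscript -e 'cat(system.file("cli","genapp",package="genapp"))') \
    generate --model model.xml --out app/
```

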