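Package: genapp
Title: Model-Driven Generation of Biological Data-Management Applications
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A compact XML modeling language for biological data structures
    (entities, typed fields, cross-references, inheritance, screen layout)
    together with a generator suite that turns a model file into a working
    data-management backend: relational schema, CRUD/REST service over an
    embedded SQLite database, foreign-key-aware tab-delimited import/export,
    human-readable documentation and an entity-relationship graph. A
    reverse-engineering path recovers a model from an existing relational
    schema so legacy databases gain generated interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    xml2,
    jsonlite,
    data.table,
    DBI,
    RSQLite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    httpuv,
    curl
Config/testthat/edition: 3
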