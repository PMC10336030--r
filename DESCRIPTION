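Package: kgforge
Title: Declarative ETL, Validation, and Reporting for Biomedical Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building versioned, provenance-stamped biomedical
    knowledge graphs from heterogeneous tabular sources and OBO ontologies.
    Provides a property-graph data model with CURIE handling and automatic
    category assignment against a pluggable Biolink-style data model; a
    KGX-style TSV exchange format with obograph-JSON ingestion and RDF
    n-triples export; a declarative, YAML-driven transform stage; a merge
    stage with table-driven identifier normalization, node reconciliation and
    edge deduplication; data-model validation with typed machine-readable
    issues; dashboard-style graph statistics including category-pair flows;
    and an end-to-end build orchestrator with cached downloads and a
    reproducible, diffable directory layout. All user-facing functions take
    and return tibbles so pipelines compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
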