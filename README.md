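# kgforge

Biomedical knowledge graphs (KGs) integrate heterogeneous assertions —
drug–target interactions, gene–disease associations, disease–phenotype
annotations, ontology hierarchies — into one directed, heterogeneous
property graph whose nodes are CURIE-identified entities (e.g. penicillin is
`CHEBI:17334`, abdominal pain is `HP:0002027`) and whose edges are typed
core triples *(subject, predicate, object)*. Building such graphs
reproducibly is mostly an engineering problem: every upstream source arrives
in its own format with its own identifiers, and without standard procedures
for typing, identifier normalization and provenance the resulting graphs are
neither comparable nor reusable.

`kgforge` is an R toolkit for constructing these graphs with a declarative,
fully auditable ETL pipeline:

* **Data model** — a pluggable, Biolink-style model (category and predicate
  trees, prefix→category and prefix→IRI maps) drives automatic typing from
  namespaces, lineage-aware validation, and category filtering that retains
  all subcategories. A miniature model ships with the package
  (`kg_mini_model()`); any YAML file of the same schema substitutes.
* **Exchange format** — KGX-style TSV (paired `nodes.tsv` / `edges.tsv`
  tables, `|`-delimited multivalued cells) with deterministic, diffable
  serialization; obograph JSON ontology ingestion; RDF n-triples export.
* **Transform** — YAML-only mapping from tabular sources to typed subgraphs
  (row filters, node/edge rules, predicate translation), each stamped with
  its source's provenance.
* **Merge** — table-driven identifier normalization (alias chains closed to
  canonical ids), first-wins node reconciliation with order-preserving list
  unions, and edge deduplication on the core-triple key with provenance
  unioned across sources.
* **Validation & statistics** — seven machine-readable rules (e.g. an HP
  phenotype identifier typed `biolink:Gene` is a
  `PREFIX_CATEGORY_CONFLICT` error), and dashboard tallies whose sums
  conserve exactly: nodes by primary category, edges by predicate, and the
  category-pair flow table behind a Sankey diagram.
* **Builds** — `run_build()` orchestrates cached download → per-source
  transform → merge → validate → stats into a date-versioned directory
  (`<workspace>/20260924/{raw,transformed/<SOURCE>,merged,validation,stats}`)
  with a sha256-digested provenance manifest and a `current` pointer that
  only moves on success. Identical inputs yield byte-identical artifacts,
  and any project can reuse another project's `transformed/<SOURCE>/`
  subgraph directly.

Everything is tibble-in/tibble-out: a graph is a pair of tibbles, results
have `tidy()`/`glance()` methods, and statistics plot with `autoplot()`.

## Worked example

The package bundles a deterministic generator that writes a complete toy
project — drug–target, gene–disease and disease–phenotype tables, a toy HP
ontology with a deprecated class, an HGNC→UniProtKB alias map, and all the
YAML configs — so the whole pipeline runs without a network connection:

```r
library(kgforge)

fx <- tempfile()
generate_fixture(fixture_spec(seed = 7), fx)
manifest <- run_build(file.path(fx, "project.yaml"), "builds")
manifest
#> <kg_manifest> build 20260924 (0.1.0) — success
#>   5 source(s), 24 output file(s)

g <- read_kgx_dir(file.path("builds", manifest$build_version, "merged"))
glance(g)
#> # A tibble: 1 × 5
#>   nodes edges categories predicates sources
#>   <int> <int>      <int>      <int>   <int>
#> 1    39    58          8          4       4

tidy(compute_stats(g))
#> # A tibble: 4 × 4
#>   subject_category          predicate               object_category           n
#> 1 biolink:ChemicalEntity    biolink:interacts_with  biolink:Protein          20
#> 2 biolink:Disease           biolink:has_phenotype   biolink:PhenotypicFeat…  12
#> 3 biolink:PhenotypicFeature biolink:subclass_of     biolink:PhenotypicFeat…  11
#> 4 biolink:Protein           biolink:associated_with biolink:Disease          15
```

The 39 nodes are the union of every entity used by the three association
tables and the ontology, after the two HGNC aliases were rewritten to their
canonical UniProtKB ids and reconciled; the 58 edges are the deduplicated
core triples (two duplicated drug–target rows collapsed, their provenance
unioned). The flow table sums to the edge total exactly, which is what makes
it readable as a Sankey diagram.

Validation reproduces the canonical mistyping example — a phenotype
identifier declared to be a gene:

```r
validate_graph(
  kg_graph(nodes = tibble::tibble(id = "HP:0002362", category = "biolink:Gene")),
  kg_mini_model())
#> # A tibble: 1 × 4
#>   rule_id                  severity target     message
#> 1 PREFIX_CATEGORY_CONFLICT error    HP:0002362 Node 'HP:0002362' is typed 'biol…
```

A thin command-line wrapper over the same functions lives at
`system.file("cli/kgforge.R", package = "kgforge")` with `download`,
`transform`, `merge`, `validate`, `stats`, `convert`, `build` and
`fixtures` subcommands (exit codes: 0 success, 1 config error, 2 validation
errors, 3 build failure).

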