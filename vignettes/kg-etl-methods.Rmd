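---
title: "Building knowledge graphs with kgforge: data model, ETL and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building knowledge graphs with kgforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgforge)
```

## The graph and its data model

`kgforge` represents a knowledge graph as a directed, heterogeneous
property graph held in two tibbles. Nodes are entities identified by CURIEs
(`prefix:local_id`; parsing splits at the *first* colon because several
biomedical sources emit local identifiers that themselves contain colons).
Each node carries an ordered category list (most specific first; the first
entry is the *primary* category used wherever a single-valued answer is
needed), an optional name and description, a `provided_by` provenance list
and arbitrary scalar properties. Edges are core triples *(subject,
predicate, object)* with an optional original-relation CURIE, provenance
(`knowledge_source`, `publications`) and arbitrary properties. Directionality
matters: `(A, p, B)` and `(B, p, A)` are different assertions.

Typing is driven by a pluggable data model (`kg_model`): two single-parent
hierarchies (entity categories, association predicates), a prefix→category
map and a prefix→IRI map. We deliberately restrict hierarchies to trees
rather than DAGs: the multiple-inheritance corners of full biomedical data
models are not needed to type, validate and filter the graphs this toolkit
targets, and a tree makes "most specific first", descendant closures and
depth-based tie-breaking unambiguous. Likewise, a prefix maps to exactly
one category; real registries occasionally overload a namespace, but a
single-valued map keeps automatic assignment auditable. Both restrictions
are stated limitations, not accidents.

`assign_categories()` returns the prefix-mapped category followed by its
ancestors up to and always including the model's default (root) category;
unmapped prefixes fall back to the root alone. Category filtering
(`filter_graph()`) expands each requested category or predicate to its full
descendant set, so filtering on `biolink:GeneOrGeneProduct` keeps `Protein`
and `Gene` nodes — subcategories are always retained. Filtering keeps
exactly the nodes incident to surviving edges, which guarantees every node
in a filtered graph has degree at least one and makes the operation
idempotent.

## Serialization

The exchange format is a KGX-style TSV pair (`nodes.tsv`, `edges.tsv`),
UTF-8, with `|` as the delimiter inside multivalued cells (the delimiter and
separator are parameters of `kgx_dialect()`). An empty cell means the
property is absent. Writing is canonical: nodes sort by id, edges by
(subject, predicate, object, knowledge_source), required columns come
first and the rest alphabetically, and all character ordering uses C-locale
radix sorting so output is byte-identical across machines and runs. That
choice is load-bearing — versioned builds are compared by digest, and
"diffable" only works if serialization is a pure function of content.

Obograph JSON ontologies ingest as follows: classes become nodes (IRIs
contracted through the prefix map by longest-base match; unmatched IRIs are
kept whole with a warning), `lbl` becomes the name, `meta.definition.val`
the description, and deprecated classes are dropped together with any edge
touching them. `is_a` edges become `biolink:subclass_of`. Every other
predicate is kept losslessly: the original predicate CURIE moves to
`relation` and the edge is typed with the generic `biolink:related_to`,
because inventing per-ontology predicate mappings silently would be worse
than a uniform, documented default.

One ordering decision deserves a note. Ontology nodes are typed with the
prefix-assigned categories first, then `biolink:OntologyClass`, then the
root. Putting `OntologyClass` first would make every ontology node's
*primary* category non-lineal with its prefix-mapped category, so a graph
containing any ontology would fail its own prefix-consistency validation
rule. With the namespace category first, an HP class is primarily a
phenotypic feature that is *also* an ontology class — which matches how the
merged graph treats it when association sources mention the same term.

N-triples export emits one `rdf:type` triple per node category, one
`rdfs:label` triple per named node, and one triple per edge, all IRIs
expanded through the model. The returned count therefore equals
Σ~nodes~(|categories| + [has name]) + |edges|, and the file's line count
equals the returned count — both facts are asserted against an independent
line-count oracle in the test suite. Labels are plain literals escaped per
the n-triples grammar; no language tags or datatypes are emitted. Lines are
sorted lexicographically, again for diffability.

## Transform

Transforms are fully declarative YAML — there is deliberately no per-source
code hook. A config names the source, the input file and format
(`tsv`/`csv`/`jsonl`/`obograph`), an ordered filter list, and node/edge
rules. Filters support `eq, ne, lt, le, gt, ge, in, not_in`; the four
comparisons coerce to numeric first and a row whose cell cannot be coerced
is dropped with a recorded warning rather than silently compared as text.
Rules can prepend a CURIE prefix to a column, fix a predicate or read it
from a column through a translation table, and map columns to properties.
Every produced node gets `provided_by = [source]`, every edge
`knowledge_source = [source]`. A row that would produce a malformed CURIE is
skipped and counted, so the report identity
`rows_read = rows_filtered + rows_errored + rows_transformed` always holds.
Within one source, duplicate node ids merge first-seen-wins for scalars
(conflicts logged) with list unions; reconciliation *across* sources is the
merge stage's job.

## Merge

Merging proceeds in three steps, each with an explicit, testable contract:

1. **Identifier normalization.** A user-supplied two-column alias→canonical
   table is closed over chains (`A→B, B→C` ⇒ `A→C`; a cycle is a
   configuration error) and every node id and edge endpoint is rewritten.
   Rewritten nodes record their previous id in the multivalued
   `original_ids` property; when an alias node and its canonical node both
   exist, the reconciled node lists both. Normalization is table-driven on
   purpose — no automatic clique merging — so the behavior is auditable
   from the map file alone.
2. **Node reconciliation.** The node set is the union over canonical ids.
   Input order is the priority order: scalar fields take the first
   non-empty value (a genuine conflict is logged, first wins), list fields
   union preserving first appearance, and categories are re-sorted most
   specific first by hierarchy depth, with ties broken stably by input
   order.
3. **Edge deduplication.** Edges collapse on the key
   *(subject, predicate, object, relation)* with `knowledge_source` and
   `publications` unioned — two sources asserting the same triple yield one
   edge with merged provenance. Free-form properties are deliberately
   excluded from the key: the same assertion with different attached scores
   is still the same assertion, and the first source's properties win.

Dangling endpoints are handled by policy: the default `stub` creates a
typed placeholder node (`provided_by = ["stub"]`, categories assigned from
the prefix) with a warning, preserving information and keeping builds from
failing on partial sources; `drop` and `error` are available where stricter
behavior is wanted. The merge report's tallies (per-source counts,
`nodes_merged`, `edges_deduplicated`, `ids_normalized`,
`dangling_handled`) are all recomputable by set arithmetic, which is how
the tests check them.

## Validation

`validate_graph()` returns a sorted tibble of typed issues instead of
throwing: builds surface all problems at once and the orchestrator decides
fatality (default: fatal, applied before the merge is written). Seven rules
cover unknown categories and predicates, unknown prefixes (warning),
missing core-triple fields, duplicate node ids, dangling edges, and
prefix–category conflicts. The conflict rule generalizes the canonical
mistyping example — a phenotype identifier typed as a gene — into a lineage
test: the primary category must be the prefix-mapped category or one of its
ancestors or descendants. Typing an HP term as the root category is a
harmless generalization; typing it as a non-lineal category like
`biolink:Gene` is an error.

## Statistics

`compute_stats()` produces the dashboard tallies: totals, nodes by primary
category, edges by predicate, per-source counts and the category-pair flow
table. Flows use primary categories only, so Σ flows = edge total exactly
— multi-counting multivalued categories would make the Sankey diagram sum
to more than the graph and become uninterpretable. `by_source` deliberately
attributes a node or edge to *every* source in its provenance list, so
those counts may sum to more than the totals; that is documented in the
report schema rather than "fixed", because the question it answers is "how
much did each source contribute", not "partition the graph".

## Builds

`run_build()` wires the stages into a versioned directory:
`raw/`, `transformed/<SOURCE>/` (each a self-contained KGX subgraph plus
its transform report), `merged/`, `validation/`, `stats/` and a
`manifest.json` listing source URLs, retrieval times, sha256 digests,
config digests and all output digests. The version stamp is the build date
(`YYYYMMDD`) with a `.n` suffix for same-day rebuilds; a `current` pointer
file is updated only on success, and a failed build keeps its partial
outputs for debugging. Downloads go through a shared cache: a cached file
matching its declared digest is reused without fetching; when a fetch
fails but a cached copy exists the build proceeds on the cache with a
warning (transient upstream outages should not break a scheduled build);
a cold-cache failure is a hard error. The local layout stands in for any
static host — the directories are exactly what one would sync to a bucket
with stable URLs, and scheduling is left to whatever runs the CLI.

Because every stage is deterministic, two builds from identical inputs are
digest-identical in `transformed/`, `merged/` and `stats/` (manifests
differ only in timestamps), and a `transformed/<SOURCE>/` directory
produced by one project can be listed as a merge input in another project
and yields a byte-identical merged graph — subgraph reuse needs no
re-transformation.

## The fixture generator

`generate_fixture()` writes a complete miniature project: a drug–target
table (CHEBI × UniProtKB with an integer score column for filter tests), a
gene–disease table whose proteins overlap the drug–target pool, a
disease–phenotype table, a toy HP ontology (an `is_a` chain over all
phenotype classes plus deprecated leaves), an HGNC→UniProtKB alias map, and
all configs. Defaults are small on purpose — 8 chemicals, 10 proteins, 6
diseases, 12 phenotypes, 20/15/12 associations, 50% protein overlap, 40%
aliasing of the shared proteins actually used, 2 duplicated rows, 1
deprecated class — sized so that every code path (filtering,
normalization, reconciliation, deduplication, deprecation, stub handling)
is exercised while a full build and its checks run in seconds; the
acceptance script runs two builds plus a reuse build at these sizes.
Aliases are drawn only from proteins already present in the drug–target
source so every alias has a canonical partner to reconcile with, and every
alias in the map is actually used, making `ids_normalized` exactly the map
size.

Ground truth is computed inside the generator by direct set arithmetic
over the rows it wrote — never by calling the transform/merge/stats code —
so pipeline-vs-ground-truth comparisons are genuine cross-checks. The
generator emulates structure, not biology: identifier overlap, aliasing
and duplication rates are uniform, there are no realistic degree
distributions, term depths, missingness patterns or upstream format
quirks. Passing tests therefore demonstrate the correctness of the ETL
contracts, not robustness to the full messiness of production sources.

## Degenerate inputs and numerical choices

Empty graphs serialize to header-only files and produce zero-valued
statistics (degree summary defined as 0). An empty filter list keeps every
row. An empty alias map is a no-op. A fixture spec with zero entities but
nonzero edges, or more requested associations than distinct pairs, is
rejected at construction. All randomized components (the fixture generator,
the in-memory random graph used for property tests) draw from their own
seeded stream and restore the caller's RNG state, so the same seed is
byte-reproducible and independent of surrounding code.

## Known limitations

Beyond the tree-hierarchy and single-map restrictions above: there is no
semantic entity resolution (string or embedding based) — normalization is
only as good as the supplied alias table; no association domain/range or
cardinality checking; no OWL parsing (ingest ontologies as obograph JSON);
no RDF import; and the HTTP download path is a plain single-attempt fetch
with cache fallback, not a retrying client. These are scope boundaries
chosen to keep every behavior in this package fully specified and testable.
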