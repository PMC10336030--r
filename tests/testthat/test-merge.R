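graph_ab <- function() {
  kg_graph(
    nodes = tibble::tibble(
      id = c("CHEBI:1", "UniProtKB:P1"),
      category = list("biolink:ChemicalEntity", "biolink:Protein"),
      provided_by = list("A", "A")),
    edges = tibble::tibble(
      subject = "CHEBI:1", predicate = "biolink:interacts_with",
      object = "UniProtKB:P1", knowledge_source = list("A")))
}

graph_bc <- function() {
  kg_graph(
    nodes = tibble::tibble(
      id = c("UniProtKB:P1", "MONDO:1"),
      category = list("biolink:Protein", "biolink:Disease"),
      provided_by = list("B", "B")),
    edges = tibble::tibble(
      subject = "UniProtKB:P1", predicate = "biolink:associated_with",
      object = "MONDO:1", knowledge_source = list("B")))
}

test_that("alias chains close to terminal canonical ids; cycles error", {
  closed <- close_id_map(tibble::tibble(alias = c("A:1", "B:1"),
                                        canonical = c("B:1", "C:1")))
  expect_equal(unname(closed[c("A:1", "B:1")]), c("C:1", "C:1"))
  expect_error(close_id_map(c("A:1" = "B:1", "B:1" = "A:1")),
               class = "kgforge_config_error")
})

test_that("identifier rewriting follows the closed map and records originals", {
  g <- kg_graph(
    nodes = tibble::tibble(id = c("A:1", "C:1"),
                           category = list("biolink:NamedThing",
                                           "biolink:NamedThing")),
    edges = tibble::tibble(subject = "A:1", predicate = "biolink:related_to",
                           object = "C:1"))
  out <- normalize_ids(g, c("A:1" = "B:1"))
  expect_setequal(out$nodes$id, c("B:1", "C:1"))
  expect_equal(out$edges$subject, "B:1")
  expect_equal(out$nodes$original_ids[[match("B:1", out$nodes$id)]], "A:1")

  # chain: A -> B -> C means a node A:x lands on C:x
  g2 <- kg_graph(nodes = tibble::tibble(id = "A:x"))
  out2 <- normalize_ids(g2, c("A:x" = "B:x", "B:x" = "C:x"))
  expect_equal(out2$nodes$id, "C:x")
})

test_that("alias and canonical nodes reconcile into one with both originals", {
  g <- kg_graph(
    nodes = tibble::tibble(
      id = c("HGNC:7", "UniProtKB:P7"),
      category = list("biolink:Gene", "biolink:Protein"),
      name = c("alias name", NA)),
    edges = tibble::tibble(
      subject = c("HGNC:7", "UniProtKB:P7"),
      predicate = "biolink:related_to",
      object = c("MONDO:1", "MONDO:2")))
  out <- suppressWarnings(normalize_ids(g, c("HGNC:7" = "UniProtKB:P7"), mini))
  expect_equal(nrow(out$nodes), 1)
  expect_equal(out$nodes$id, "UniProtKB:P7")
  expect_setequal(out$nodes$original_ids[[1]], c("HGNC:7", "UniProtKB:P7"))
  expect_equal(nrow(out$edges), 2)
  expect_true(all(out$edges$subject == "UniProtKB:P7"))
  # categories unioned, re-sorted most specific first, same-depth stable
  expect_equal(out$nodes$category[[1]][1], "biolink:Gene")
})

test_that("node conflicts resolve first-non-empty with unions for lists", {
  a <- tibble::tibble(id = "HGNC:1", category = list("biolink:Gene"),
                      name = "TP53", provided_by = list("S1"))
  b <- tibble::tibble(id = "HGNC:1", category = list("biolink:Gene"),
                      provided_by = list("S2"))
  merged <- resolve_node_conflicts(a, b)
  expect_equal(merged$name, "TP53")
  expect_equal(merged$provided_by[[1]], c("S1", "S2"))

  b$name <- "p53"
  expect_warning(merged <- resolve_node_conflicts(a, b), "conflict")
  expect_equal(merged$name, "TP53")
})

test_that("merging unions nodes and deduplicates edges with provenance", {
  res <- merge_graphs(list(A = graph_ab(), B = graph_bc()), mini)
  expect_equal(res$report$node_total, 3)
  expect_equal(res$report$edge_total, 2)
  expect_equal(res$report$nodes_merged, 1)  # UniProtKB:P1 in both

  # identical core triples from two sources collapse, knowledge_source unioned
  dup <- graph_ab()
  dup$edges$knowledge_source <- list("B")
  dup$nodes$provided_by <- list("B", "B")
  res2 <- merge_graphs(list(A = graph_ab(), B = dup), mini)
  expect_equal(res2$report$edge_total, 1)
  expect_equal(res2$report$edges_deduplicated, 1)
  expect_equal(res2$graph$edges$knowledge_source[[1]], c("A", "B"))
  node <- res2$graph$nodes[res2$graph$nodes$id == "CHEBI:1", ]
  expect_equal(node$provided_by[[1]], c("A", "B"))
})

test_that("merge is idempotent and permutation-invariant on sets", {
  g <- graph_ab()
  once <- merge_graphs(list(g), mini)
  twice <- merge_graphs(list(g, g), mini)
  expect_true(kg_equal(once$graph, twice$graph))

  ab <- merge_graphs(list(A = graph_ab(), B = graph_bc()), mini)
  ba <- merge_graphs(list(B = graph_bc(), A = graph_ab()), mini)
  expect_setequal(ab$graph$nodes$id, ba$graph$nodes$id)
  key <- function(g) paste(g$edges$subject, g$edges$predicate, g$edges$object)
  expect_setequal(key(ab$graph), key(ba$graph))
})

test_that("merged size is bounded by input sizes with equality iff disjoint", {
  a <- graph_ab(); b <- graph_bc()
  res <- merge_graphs(list(a, b), mini)
  expect_lte(res$report$node_total, nrow(a$nodes) + nrow(b$nodes))
  expect_lte(res$report$edge_total, nrow(a$edges) + nrow(b$edges))
  # disjoint inputs: sizes add exactly
  c_ <- kg_graph(nodes = tibble::tibble(id = "GO:1",
                                        category = "biolink:OntologyClass"))
  res2 <- merge_graphs(list(a, c_), mini)
  expect_equal(res2$report$node_total, nrow(a$nodes) + 1)
})

test_that("dangling endpoints honor the configured policy", {
  g <- kg_graph(
    nodes = tibble::tibble(id = "CHEBI:1",
                           category = list("biolink:ChemicalEntity")),
    edges = tibble::tibble(subject = "CHEBI:1",
                           predicate = "biolink:interacts_with",
                           object = "UniProtKB:Q9"))
  expect_warning(res <- merge_graphs(list(g), mini, on_dangling = "stub"),
                 "stub")
  expect_equal(res$report$dangling_handled, 1)
  stub <- res$graph$nodes[res$graph$nodes$id == "UniProtKB:Q9", ]
  expect_equal(stub$provided_by[[1]], "stub")
  expect_equal(stub$category[[1]][1], "biolink:Protein")

  res_drop <- merge_graphs(list(g), mini, on_dangling = "drop")
  expect_equal(nrow(res_drop$graph$edges), 0)

  err <- tryCatch(merge_graphs(list(g), mini, on_dangling = "error"),
                  error = identity)
  expect_s3_class(err, "kgforge_merge_error")
  expect_match(conditionMessage(err), "UniProtKB:Q9")
})

test_that("merge reports are recomputable by set arithmetic on fixtures", {
  fx <- withr::local_tempdir()
  gt <- generate_fixture(fixture_spec(seed = 21), fx)$ground_truth
  model <- read_model(file.path(fx, "model.yaml"))
  srcs <- c("drug_target", "gene_disease", "disease_phenotype", "hp_ontology")
  graphs <- purrr::map(file.path(fx, "config", paste0(srcs, ".yaml")),
                       function(p) {
                         suppressWarnings(transform_source(
                           p, model,
                           input_dir = file.path(fx, "sources")))$graph
                       })
  names(graphs) <- srcs
  res <- suppressWarnings(merge_graphs(
    graphs, model, id_map = file.path(fx, "sources", "id_map.tsv")))
  expect_equal(res$report$node_total, gt$merged$node_total)
  expect_equal(res$report$edge_total, gt$merged$edge_total)
  expect_equal(res$report$ids_normalized, gt$merged$ids_normalized)
  expect_equal(res$report$edges_deduplicated, gt$merged$edges_deduplicated)
  expect_equal(res$report$dangling_handled, gt$merged$dangling_handled)
})
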