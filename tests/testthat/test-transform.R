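write_drug_target <- function(dir, rows) {
  path <- file.path(dir, "dt.tsv")
  readr::write_tsv(rows, path)
  path
}

dt_config <- function(dir, input = "dt.tsv", filters = list()) {
  cfg <- list(
    source_name = "dt",
    input_file = input,
    format = "tsv",
    filters = filters,
    nodes = list(
      list(id_column = "chem"),
      list(id_column = "prot", prefix = "UniProtKB:")
    ),
    edges = list(
      list(subject_column = "chem", predicate = "biolink:interacts_with",
           object_column = "prot", object_prefix = "UniProtKB:",
           properties = list(score = "score"))
    )
  )
  path <- file.path(dir, "dt.yaml")
  yaml::write_yaml(cfg, path)
  path
}

test_that("filter rules implement the full operator set", {
  d <- tibble::tibble(score = c("700", "300", "n/a"),
                      taxon = c("9606", "10090", "7955"))
  expect_equal(apply_filters(d, list(list(column = "score", op = "ge",
                                          value = 500)))$keep,
               c(TRUE, FALSE, FALSE))
  res <- apply_filters(d, list(list(column = "score", op = "ge", value = 500)))
  expect_match(res$warnings, "n/a")  # coercion failure drops the row, warned
  expect_equal(apply_filters(d, list(list(column = "taxon", op = "in",
                                          value = list("9606", "10090"))))$keep,
               c(TRUE, TRUE, FALSE))
  expect_equal(apply_filters(d, list(list(column = "taxon", op = "not_in",
                                          value = list("9606"))))$keep,
               c(FALSE, TRUE, TRUE))
  expect_equal(apply_filters(d, list(list(column = "taxon", op = "eq",
                                          value = "9606")))$keep,
               c(TRUE, FALSE, FALSE))
  expect_equal(apply_filters(d, list(list(column = "score", op = "lt",
                                          value = 500)))$keep,
               c(FALSE, TRUE, FALSE))
  # conjunction of rules; empty list keeps everything
  expect_equal(apply_filters(d, list())$keep, rep(TRUE, 3))
  both <- apply_filters(d, list(list(column = "score", op = "ge", value = 500),
                                list(column = "taxon", op = "eq",
                                     value = "9606")))
  expect_equal(both$keep, c(TRUE, FALSE, FALSE))
  expect_error(apply_filters(d, list(list(column = "absent", op = "eq",
                                          value = "x"))),
               class = "kgforge_config_error")
})

test_that("a tabular source becomes a provenance-stamped typed subgraph", {
  dir <- withr::local_tempdir()
  rows <- tibble::tibble(chem = c("CHEBI:1", "CHEBI:2", "CHEBI:1"),
                         prot = c("P1", "P1", "P2"),
                         score = c(900, 400, 700))
  write_drug_target(dir, rows)
  res <- transform_source(dt_config(dir), mini)
  # 3 rows x 2 node emissions dedup to unique ids
  expect_equal(nrow(res$graph$nodes), 4)
  expect_equal(nrow(res$graph$edges), 3)
  expect_true(all(purrr::map_lgl(res$graph$nodes$provided_by,
                                 ~ identical(.x, "dt"))))
  expect_true(all(purrr::map_lgl(res$graph$edges$knowledge_source,
                                 ~ identical(.x, "dt"))))
  # typing came from the prefix maps
  chem <- res$graph$nodes$category[[match("CHEBI:1", res$graph$nodes$id)]]
  expect_equal(chem[1], "biolink:ChemicalEntity")
  prot <- res$graph$nodes$category[[match("UniProtKB:P1", res$graph$nodes$id)]]
  expect_equal(prot[1], "biolink:Protein")
  expect_equal(res$graph$edges$score, c("900", "400", "700"))
})

test_that("transform report arithmetic balances", {
  dir <- withr::local_tempdir()
  rows <- tibble::tibble(chem = c("CHEBI:1", "CHEBI:2", "CHEBI:3", "bad id"),
                         prot = c("P1", "P2", "P3", "P4"),
                         score = c("900", "400", "oops", "800"))
  write_drug_target(dir, rows)
  cfg <- dt_config(dir, filters = list(list(column = "score", op = "ge",
                                            value = 500)))
  res <- transform_source(cfg, mini)
  r <- res$report
  expect_equal(r$rows_read, 4)
  expect_equal(r$rows_filtered, 2)   # score 400 + uncoercible "oops"
  expect_equal(r$rows_errored, 1)    # "bad id" is not a CURIE
  expect_equal(r$rows_read, r$rows_filtered + r$rows_errored +
                 r$rows_transformed)
  expect_equal(r$edges, 1)
  expect_gt(length(r$warnings), 0)
})

test_that("transform output is deterministic given config and input bytes", {
  dir <- withr::local_tempdir()
  rows <- tibble::tibble(chem = sprintf("CHEBI:%d", 1:5),
                         prot = sprintf("P%d", 5:1),
                         score = 1:5 * 100)
  write_drug_target(dir, rows)
  cfg <- dt_config(dir)
  g1 <- transform_source(cfg, mini)$graph
  g2 <- transform_source(cfg, mini)$graph
  expect_true(kg_equal(g1, g2))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_kgx(g1, d1); write_kgx(g2, d2)
  expect_identical(readLines(file.path(d1, "nodes.tsv")),
                   readLines(file.path(d2, "nodes.tsv")))
})

test_that("duplicate node ids within a source merge first-seen-wins", {
  dir <- withr::local_tempdir()
  readr::write_tsv(tibble::tibble(
    id = c("MONDO:1", "MONDO:1"), nm = c("first name", "second name"),
    phe = c("HP:1", "HP:2")), file.path(dir, "src.tsv"))
  yaml::write_yaml(list(
    source_name = "dd", input_file = "src.tsv", format = "tsv",
    nodes = list(list(id_column = "id", name_column = "nm"),
                 list(id_column = "phe")),
    edges = list(list(subject_column = "id",
                      predicate = "biolink:has_phenotype",
                      object_column = "phe"))
  ), file.path(dir, "dd.yaml"))
  res <- transform_source(file.path(dir, "dd.yaml"), mini)
  node <- res$graph$nodes[res$graph$nodes$id == "MONDO:1", ]
  expect_equal(node$name, "first name")
  expect_match(unlist(res$report$warnings), "conflicting", all = FALSE)
})

test_that("a predicate column routes through the translation table", {
  dir <- withr::local_tempdir()
  readr::write_tsv(tibble::tibble(
    s = c("CHEBI:1", "CHEBI:2"), rel = c("binds", "treats_disease"),
    o = c("UniProtKB:P1", "MONDO:1")), file.path(dir, "src.tsv"))
  yaml::write_yaml(list(
    source_name = "pm", input_file = "src.tsv", format = "tsv",
    nodes = list(list(id_column = "s"), list(id_column = "o")),
    edges = list(list(subject_column = "s", predicate_column = "rel",
                      predicate_map = list(binds = "biolink:interacts_with",
                                           treats_disease = "biolink:treats"),
                      object_column = "o"))
  ), file.path(dir, "pm.yaml"))
  res <- transform_source(file.path(dir, "pm.yaml"), mini)
  expect_equal(res$graph$edges$predicate,
               c("biolink:interacts_with", "biolink:treats"))
})

test_that("a category override applies with its ancestors", {
  dir <- withr::local_tempdir()
  readr::write_tsv(tibble::tibble(id = "XI:1", other = "XI:2"),
                   file.path(dir, "src.tsv"))
  yaml::write_yaml(list(
    source_name = "ov", input_file = "src.tsv", format = "tsv",
    nodes = list(list(id_column = "id", category = "biolink:Protein"),
                 list(id_column = "other")),
    edges = list(list(subject_column = "id", predicate = "biolink:related_to",
                      object_column = "other"))
  ), file.path(dir, "ov.yaml"))
  res <- transform_source(file.path(dir, "ov.yaml"), mini)
  cats <- res$graph$nodes$category[[match("XI:1", res$graph$nodes$id)]]
  expect_equal(cats, c("biolink:Protein", "biolink:GeneOrGeneProduct",
                       "biolink:NamedThing"))
})

test_that("missing referenced columns fail at config application, not per row", {
  dir <- withr::local_tempdir()
  write_drug_target(dir, tibble::tibble(chem = "CHEBI:1", prot = "P1",
                                        score = 1))
  cfg <- dt_config(dir, filters = list(list(column = "nonexistent", op = "eq",
                                            value = "x")))
  expect_error(transform_source(cfg, mini), class = "kgforge_config_error")
})
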