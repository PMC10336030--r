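# A small fixture project shared by the build tests (generated once per run).
local_fixture_build <- function(env = parent.frame(), seed = 7) {
  fx <- withr::local_tempdir(.local_envir = env)
  gt <- generate_fixture(fixture_spec(seed = seed), fx)$ground_truth
  ws <- withr::local_tempdir(.local_envir = env)
  man <- suppressWarnings(run_build(file.path(fx, "project.yaml"), ws))
  list(fx = fx, ws = ws, gt = gt, manifest = man,
       build_dir = file.path(ws, man$build_version))
}

test_that("cached retrieval reuses files and survives unreachable sources", {
  src_dir <- withr::local_tempdir()
  writeLines(c("id\tname", "CHEBI:1\tx"), file.path(src_dir, "a.tsv"))
  cache <- withr::local_tempdir()
  specs <- list(list(url = paste0("file:", src_dir, "/a.tsv"),
                     local_name = "a.tsv"))
  first <- fetch_sources(specs, cache)
  expect_false(first$cache_hit)
  second <- fetch_sources(specs, cache)
  expect_true(second$cache_hit)

  # unreachable source + warm cache: reuse with a warning
  gone <- list(list(url = "file:/nonexistent/missing.tsv",
                    local_name = "a.tsv", sha256 = "mismatch-forces-refetch"))
  expect_warning(res <- fetch_sources(gone, cache), "cached copy")
  expect_true(res$cache_hit)

  # unreachable and cold: hard error naming the source
  err <- tryCatch(
    fetch_sources(list(list(url = "file:/nonexistent/missing.tsv",
                            local_name = "cold.tsv")), cache),
    error = identity)
  expect_s3_class(err, "kgforge_io_error")
  expect_match(conditionMessage(err), "cold.tsv")

  # offline forbids fetching and requires cache
  expect_error(fetch_sources(list(list(url = "file:whatever",
                                       local_name = "never-seen.tsv")),
                             cache, offline = TRUE),
               class = "kgforge_io_error")
})

test_that("a build produces the versioned layout with a manifest", {
  b <- local_fixture_build()
  expect_match(b$manifest$build_version, "^[0-9]{8}(\\.[0-9]+)?$")
  for (sub in c("raw", "transformed/drug_target", "transformed/gene_disease",
                "transformed/disease_phenotype", "transformed/hp_ontology",
                "merged", "validation", "stats")) {
    expect_true(dir.exists(file.path(b$build_dir, sub)), info = sub)
  }
  man <- jsonlite::fromJSON(file.path(b$build_dir, "manifest.json"),
                            simplifyVector = FALSE)
  expect_equal(man$status, "success")
  expect_length(man$sources, 5)
  expect_true(all(vapply(man$outputs, function(o) nzchar(o$sha256),
                         logical(1))))
  expect_equal(readLines(file.path(b$ws, "current")),
               b$manifest$build_version)

  # every transformed subgraph is independently loadable KGX
  for (src in c("drug_target", "gene_disease", "disease_phenotype",
                "hp_ontology")) {
    g <- read_kgx_dir(file.path(b$build_dir, "transformed", src))
    expect_gt(nrow(g$nodes), 0)
  }
})

test_that("the built artifacts match the generator's ground truth", {
  b <- local_fixture_build()
  merged <- read_kgx_dir(file.path(b$build_dir, "merged"))
  expect_equal(nrow(merged$nodes), b$gt$merged$node_total)
  expect_equal(nrow(merged$edges), b$gt$merged$edge_total)
  rep <- jsonlite::fromJSON(file.path(b$build_dir, "merged",
                                      "merge_report.json"))
  expect_equal(rep$ids_normalized, b$gt$merged$ids_normalized)
  expect_equal(rep$edges_deduplicated, b$gt$merged$edges_deduplicated)
  st <- jsonlite::fromJSON(file.path(b$build_dir, "stats", "stats.json"))
  expect_equal(st$node_total, b$gt$stats$node_total)
  expect_equal(st$nodes_by_category[order(names(st$nodes_by_category))],
               lapply(b$gt$stats$nodes_by_category, as.integer)[
                 order(names(b$gt$stats$nodes_by_category))])
  expect_equal(st$edges_by_predicate,
               lapply(b$gt$stats$edges_by_predicate, as.integer))
  # per-source transform reports
  for (src in names(b$gt$per_source)) {
    tr <- jsonlite::fromJSON(file.path(b$build_dir, "transformed", src,
                                       "transform_report.json"))
    expect_equal(tr$nodes, b$gt$per_source[[src]]$nodes, info = src)
    expect_equal(tr$edges, b$gt$per_source[[src]]$edges, info = src)
    expect_equal(tr$rows_read,
                 tr$rows_filtered + tr$rows_errored + tr$rows_transformed)
  }
})

test_that("rebuilding identical inputs is digest-identical with a .n suffix", {
  b <- local_fixture_build()
  man2 <- suppressWarnings(run_build(file.path(b$fx, "project.yaml"), b$ws))
  expect_match(man2$build_version, "\\.[0-9]+$")
  expect_equal(readLines(file.path(b$ws, "current")), man2$build_version)
  pick <- function(v) {
    fs <- list.files(file.path(b$ws, v), recursive = TRUE)
    fs <- fs[grepl("^(transformed|merged|stats)/", fs)]
    vapply(fs, function(f) {
      digest::digest(file = file.path(b$ws, v, f), algo = "sha256")
    }, character(1))
  }
  expect_identical(pick(b$manifest$build_version), pick(man2$build_version))
})

test_that("a validation failure aborts before merge and keeps current intact", {
  fx <- withr::local_tempdir()
  generate_fixture(fixture_spec(seed = 7), fx)
  # corrupt one source: type a phenotype column as genes via category override
  yaml::write_yaml(list(
    source_name = "disease_phenotype",
    input_file = "disease_phenotype.tsv",
    format = "tsv",
    nodes = list(list(id_column = "disease_id"),
                 list(id_column = "phenotype_id", category = "biolink:Gene")),
    edges = list(list(subject_column = "disease_id",
                      predicate = "biolink:has_phenotype",
                      object_column = "phenotype_id"))
  ), file.path(fx, "config", "disease_phenotype.yaml"))
  ws <- withr::local_tempdir()
  err <- tryCatch(suppressWarnings(run_build(file.path(fx, "project.yaml"), ws)),
                  error = identity)
  expect_s3_class(err, "kgforge_build_error")
  expect_match(conditionMessage(err), "validation")
  vs <- setdiff(list.dirs(ws, recursive = FALSE, full.names = FALSE), "cache")
  expect_length(vs, 1)
  expect_false(dir.exists(file.path(ws, vs, "merged")))   # aborted pre-merge
  expect_true(dir.exists(file.path(ws, vs, "transformed")))  # kept for debugging
  expect_false(file.exists(file.path(ws, "current")))
  man <- jsonlite::fromJSON(file.path(ws, vs, "manifest.json"))
  expect_match(man$status, "failed")
})

test_that("a transformed subgraph from one project merges identically in another", {
  b <- local_fixture_build()
  # second project reuses the first build's transformed/drug_target directory
  fx2 <- withr::local_tempdir()
  generate_fixture(fixture_spec(seed = 7), fx2)
  upstream <- file.path(b$build_dir, "transformed", "drug_target")
  yaml::write_yaml(list(
    inputs = list(upstream, "gene_disease", "disease_phenotype",
                  "hp_ontology"),
    id_map = "id_map.tsv",
    on_dangling = "stub", output = "merged"
  ), file.path(fx2, "config", "merge.yaml"))
  ws2 <- withr::local_tempdir()
  man2 <- suppressWarnings(run_build(file.path(fx2, "project.yaml"), ws2))
  f1 <- file.path(b$build_dir, "merged")
  f2 <- file.path(ws2, man2$build_version, "merged")
  expect_identical(readLines(file.path(f1, "nodes.tsv")),
                   readLines(file.path(f2, "nodes.tsv")))
  expect_identical(readLines(file.path(f1, "edges.tsv")),
                   readLines(file.path(f2, "edges.tsv")))
})
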