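#' Specification for a deterministic toy knowledge-graph project
#'
#' Describes the miniature drug-protein-disease-phenotype project emitted by
#' [generate_fixture()]: entity pool sizes, association counts per table,
#' the fraction of protein identifiers shared between the drug-target and
#' gene-disease sources, the fraction of shared proteins written under an
#' HGNC alias (exercising identifier normalization), the number of
#' duplicated association rows (exercising edge deduplication) and the
#' number of deprecated ontology classes. The same seed and spec always
#' yield byte-identical files and identical ground-truth tallies.
#'
#' @param seed Integer seed for the generator's own random stream.
#' @param n_chemicals,n_proteins,n_diseases,n_phenotypes Entity pool sizes.
#' @param n_chemical_protein,n_gene_disease,n_disease_phenotype Association
#'   counts for the three tabular sources.
#' @param overlap_fraction Fraction of the gene-disease source's proteins
#'   drawn from proteins already used by the drug-target source.
#' @param alias_fraction Fraction of those shared proteins written as HGNC
#'   aliases (each alias gets an id-map row to its canonical UniProtKB id).
#' @param n_duplicate_rows Drug-target rows repeated verbatim.
#' @param n_deprecated Deprecated classes added to the toy ontology.
#' @return A list of class `kg_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_chemicals = 8L, n_proteins = 10L,
                         n_diseases = 6L, n_phenotypes = 12L,
                         n_chemical_protein = 20L, n_gene_disease = 15L,
                         n_disease_phenotype = 12L, overlap_fraction = 0.5,
                         alias_fraction = 0.4, n_duplicate_rows = 2L,
                         n_deprecated = 1L) {
  spec <- list(
    seed = as.integer(seed), n_chemicals = as.integer(n_chemicals),
    n_proteins = as.integer(n_proteins), n_diseases = as.integer(n_diseases),
    n_phenotypes = as.integer(n_phenotypes),
    n_chemical_protein = as.integer(n_chemical_protein),
    n_gene_disease = as.integer(n_gene_disease),
    n_disease_phenotype = as.integer(n_disease_phenotype),
    overlap_fraction = overlap_fraction, alias_fraction = alias_fraction,
    n_duplicate_rows = as.integer(n_duplicate_rows),
    n_deprecated = as.integer(n_deprecated)
  )
  counts <- unlist(spec[c("n_chemicals", "n_proteins", "n_diseases",
                          "n_phenotypes")])
  edges <- unlist(spec[c("n_chemical_protein", "n_gene_disease",
                         "n_disease_phenotype")])
  if (any(counts <= 0) && any(edges > 0)) {
    abort("Degenerate fixture spec: zero entities with nonzero edges",
          class = "kgforge_config_error")
  }
  if (spec$n_chemical_protein > spec$n_chemicals * spec$n_proteins ||
      spec$n_gene_disease > spec$n_proteins * spec$n_diseases ||
      spec$n_disease_phenotype > spec$n_diseases * spec$n_phenotypes) {
    abort("Fixture spec requests more distinct associations than pairs exist",
          class = "kgforge_config_error")
  }
  structure(spec, class = "kg_fixture_spec")
}

sample_pairs <- function(a, b, n) {
  grid <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
  grid[sample.int(nrow(grid), n), , drop = FALSE]
}

#' Generate a toy knowledge-graph project with ground truth
#'
#' Writes a complete, self-contained miniature project under `out_dir`: a
#' drug-target TSV with a numeric score column, a gene-disease TSV sharing
#' protein identifiers with it (some under HGNC aliases), a
#' disease-phenotype TSV, a toy obograph JSON phenotype ontology with `is_a`
#' chains and deprecated classes, an alias-to-canonical id map, a copy of
#' the miniature data model, and download/transform/merge/project YAML
#' configs so [run_build()] runs end to end on it with no network. All
#' configs use relative `file:` URLs, so two runs of the same spec are
#' digest-identical wherever they land.
#'
#' `ground_truth.json` holds the expected tallies — unique ids per prefix,
#' merged node/edge counts, normalization/deduplication counts and the
#' statistics sums — computed here by direct set arithmetic over the rows
#' written, independently of the ETL implementation, so the pipeline can be
#' checked against it.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with `paths` (named file paths) and
#'   `ground_truth` (the tally list).
#' @export
generate_fixture <- function(spec = fixture_spec(), out_dir) {
  stopifnot(inherits(spec, "kg_fixture_spec"))
  dir.create(file.path(out_dir, "sources"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "config"), showWarnings = FALSE)

  withr::with_seed(spec$seed, {
    chemicals <- sprintf("CHEBI:%05d", sort(sample.int(99999, spec$n_chemicals)))
    proteins <- sprintf("P%05d", sort(sample.int(99999, spec$n_proteins)))
    diseases <- sprintf("MONDO:%07d", sort(sample.int(9999999, spec$n_diseases)))
    phenotypes <- sprintf("HP:%07d", sort(sample.int(9999999, spec$n_phenotypes)))

    # (a) drug-target: CHEBI x UniProtKB with a 0-1000 score
    cp <- sample_pairs(chemicals, proteins, spec$n_chemical_protein)
    cp$score <- sample.int(1000, nrow(cp), replace = TRUE)
    if (spec$n_duplicate_rows > 0) {
      cp <- rbind(cp, cp[seq_len(min(spec$n_duplicate_rows, nrow(cp))), ,
                         drop = FALSE])
    }
    drug_target <- tibble::tibble(
      chemical_id = cp$a, protein_id = cp$b, score = cp$score
    )

    # (b) gene-disease: proteins drawn from the drug-target pool per
    # overlap_fraction, the rest fresh; a fraction of the shared proteins
    # actually used are written as HGNC aliases (all their occurrences)
    used_cp_proteins <- unique(cp$b)
    n_shared <- round(spec$overlap_fraction * spec$n_proteins)
    n_shared <- min(n_shared, length(used_cp_proteins))
    shared <- sort(sample(used_cp_proteins, n_shared))
    fresh <- sprintf("Q%05d", sort(sample.int(99999,
                                              spec$n_proteins - n_shared)))
    gd_pool <- c(shared, fresh)
    gd <- sample_pairs(gd_pool, diseases, spec$n_gene_disease)
    used_shared <- sort(intersect(unique(gd$a), shared))
    n_alias <- round(spec$alias_fraction * length(used_shared))
    aliased <- sort(sample(used_shared, n_alias))
    alias_of <- stats::setNames(sprintf("%05d", sample.int(99999, n_alias)),
                                aliased)
    gd$a_out <- ifelse(gd$a %in% aliased,
                       paste0("HGNC:", alias_of[gd$a]),
                       paste0("UniProtKB:", gd$a))
    gene_disease <- tibble::tibble(gene_id = gd$a_out, disease_id = gd$b)

    # (c) disease-phenotype
    dp <- sample_pairs(diseases, phenotypes, spec$n_disease_phenotype)
    disease_phenotype <- tibble::tibble(disease_id = dp$a, phenotype_id = dp$b)

    # (d) toy ontology: is_a chain over all phenotype classes, plus
    # deprecated leaves outside the chain
    deprecated <- if (spec$n_deprecated > 0) {
      sprintf("HP:%07d", 9000000 + seq_len(spec$n_deprecated))
    } else character()
  })

  id_map <- tibble::tibble(
    alias = paste0("HGNC:", unname(alias_of)),
    canonical = paste0("UniProtKB:", names(alias_of))
  )
  id_map <- id_map[order_c(id_map$alias), , drop = FALSE]

  obo_iri <- function(x) paste0("http://purl.obolibrary.org/obo/",
                                sub(":", "_", x))
  onto_nodes <- c(
    purrr::map(seq_along(phenotypes), function(i) {
      list(id = obo_iri(phenotypes[i]),
           lbl = sprintf("toy phenotype %d", i),
           type = "CLASS",
           meta = list(definition = list(
             val = sprintf("Synthetic phenotype class %d.", i))))
    }),
    purrr::map(seq_along(deprecated), function(i) {
      list(id = obo_iri(deprecated[i]),
           lbl = sprintf("obsolete toy phenotype %d", i),
           type = "CLASS",
           meta = list(deprecated = TRUE))
    })
  )
  onto_edges <- purrr::map(seq_len(length(phenotypes) - 1), function(i) {
    list(sub = obo_iri(phenotypes[i + 1]), pred = "is_a",
         obj = obo_iri(phenotypes[i]))
  })
  ontology <- list(graphs = list(list(
    id = "http://example.org/toy-hp.json",
    nodes = onto_nodes, edges = onto_edges
  )))

  paths <- c(
    drug_target = file.path(out_dir, "sources", "drug_target.tsv"),
    gene_disease = file.path(out_dir, "sources", "gene_disease.tsv"),
    disease_phenotype = file.path(out_dir, "sources", "disease_phenotype.tsv"),
    ontology = file.path(out_dir, "sources", "hp_ontology.json"),
    id_map = file.path(out_dir, "sources", "id_map.tsv"),
    model = file.path(out_dir, "model.yaml"),
    project = file.path(out_dir, "project.yaml"),
    ground_truth = file.path(out_dir, "ground_truth.json")
  )
  wt <- function(x, p) readr::write_tsv(x, p, quote = "none", escape = "none",
                                        progress = FALSE)
  wt(drug_target, paths[["drug_target"]])
  wt(gene_disease, paths[["gene_disease"]])
  wt(disease_phenotype, paths[["disease_phenotype"]])
  wt(id_map, paths[["id_map"]])
  write_json_file(ontology, paths[["ontology"]], pretty = TRUE)
  file.copy(system.file("extdata", "mini-model.yaml", package = "kgforge",
                        mustWork = TRUE), paths[["model"]], overwrite = TRUE)
  write_fixture_configs(out_dir)

  gt <- fixture_ground_truth(spec, drug_target, gene_disease,
                             disease_phenotype, phenotypes, deprecated,
                             id_map)
  write_json_file(gt, paths[["ground_truth"]])
  invisible(list(paths = paths, ground_truth = gt))
}

write_fixture_configs <- function(out_dir) {
  cfg <- file.path(out_dir, "config")
  yaml::write_yaml(list(
    downloads = list(
      list(url = "file:../sources/drug_target.tsv",
           local_name = "drug_target.tsv"),
      list(url = "file:../sources/gene_disease.tsv",
           local_name = "gene_disease.tsv"),
      list(url = "file:../sources/disease_phenotype.tsv",
           local_name = "disease_phenotype.tsv"),
      list(url = "file:../sources/hp_ontology.json",
           local_name = "hp_ontology.json"),
      list(url = "file:../sources/id_map.tsv", local_name = "id_map.tsv")
    )
  ), file.path(cfg, "download.yaml"))

  yaml::write_yaml(list(
    source_name = "drug_target",
    input_file = "drug_target.tsv",
    format = "tsv",
    filters = list(list(column = "score", op = "ge", value = 0)),
    nodes = list(
      list(id_column = "chemical_id"),
      list(id_column = "protein_id", prefix = "UniProtKB:")
    ),
    edges = list(
      list(subject_column = "chemical_id",
           predicate = "biolink:interacts_with",
           object_column = "protein_id", object_prefix = "UniProtKB:",
           properties = list(score = "score"))
    )
  ), file.path(cfg, "drug_target.yaml"))

  yaml::write_yaml(list(
    source_name = "gene_disease",
    input_file = "gene_disease.tsv",
    format = "tsv",
    nodes = list(
      list(id_column = "gene_id"),
      list(id_column = "disease_id")
    ),
    edges = list(
      list(subject_column = "gene_id",
           predicate = "biolink:associated_with",
           object_column = "disease_id")
    )
  ), file.path(cfg, "gene_disease.yaml"))

  yaml::write_yaml(list(
    source_name = "disease_phenotype",
    input_file = "disease_phenotype.tsv",
    format = "tsv",
    nodes = list(
      list(id_column = "disease_id"),
      list(id_column = "phenotype_id")
    ),
    edges = list(
      list(subject_column = "disease_id",
           predicate = "biolink:has_phenotype",
           object_column = "phenotype_id")
    )
  ), file.path(cfg, "disease_phenotype.yaml"))

  yaml::write_yaml(list(
    source_name = "hp_ontology",
    input_file = "hp_ontology.json",
    format = "obograph"
  ), file.path(cfg, "hp_ontology.yaml"))

  yaml::write_yaml(list(
    inputs = list("drug_target", "gene_disease", "disease_phenotype",
                  "hp_ontology"),
    id_map = "id_map.tsv",
    on_dangling = "stub",
    output = "merged"
  ), file.path(cfg, "merge.yaml"))

  yaml::write_yaml(list(
    model = "model.yaml",
    download = "config/download.yaml",
    transforms = list("config/drug_target.yaml", "config/gene_disease.yaml",
                      "config/disease_phenotype.yaml",
                      "config/hp_ontology.yaml"),
    merge = "config/merge.yaml",
    validation_fatal = TRUE
  ), file.path(out_dir, "project.yaml"))
}

# Expected tallies by direct set arithmetic over the written rows — no call
# into the transform/merge/stats code paths.
fixture_ground_truth <- function(spec, drug_target, gene_disease,
                                 disease_phenotype, phenotypes, deprecated,
                                 id_map) {
  canon <- stats::setNames(id_map$canonical, id_map$alias)
  canonize <- function(x) ifelse(x %in% names(canon), canon[x], x)

  cp_chem <- unique(drug_target$chemical_id)
  cp_prot <- unique(paste0("UniProtKB:", drug_target$protein_id))
  gd_gene_raw <- unique(gene_disease$gene_id)
  gd_gene <- unique(unname(canonize(gd_gene_raw)))
  gd_dis <- unique(gene_disease$disease_id)
  dp_dis <- unique(disease_phenotype$disease_id)
  dp_phe <- unique(disease_phenotype$phenotype_id)

  all_proteins <- union(cp_prot, gd_gene)
  all_diseases <- union(gd_dis, dp_dis)
  all_phenotypes <- union(dp_phe, phenotypes)  # ontology covers all classes

  node_total <- length(cp_chem) + length(all_proteins) +
    length(all_diseases) + length(all_phenotypes)

  cp_triples <- unique(paste(drug_target$chemical_id,
                             drug_target$protein_id))
  gd_triples <- unique(paste(canonize(gene_disease$gene_id),
                             gene_disease$disease_id))
  dp_triples <- unique(paste(disease_phenotype$disease_id,
                             disease_phenotype$phenotype_id))
  n_isa <- length(phenotypes) - 1L
  edge_total <- length(cp_triples) + length(gd_triples) +
    length(dp_triples) + n_isa

  # primary categories: every alias is drawn from proteins already present
  # in the drug-target source, so after normalization every protein node's
  # primary category is Protein (the aliased nodes gain Gene as a secondary
  # category); HP classes keep PhenotypicFeature primary
  nodes_by_category <- list(
    "biolink:ChemicalEntity" = length(cp_chem),
    "biolink:Disease" = length(all_diseases),
    "biolink:PhenotypicFeature" = length(all_phenotypes),
    "biolink:Protein" = length(all_proteins)
  )

  sankey <- list(
    list(subject_category = "biolink:ChemicalEntity",
         predicate = "biolink:interacts_with",
         object_category = "biolink:Protein", n = length(cp_triples)),
    list(subject_category = "biolink:Disease",
         predicate = "biolink:has_phenotype",
         object_category = "biolink:PhenotypicFeature",
         n = length(dp_triples)),
    list(subject_category = "biolink:PhenotypicFeature",
         predicate = "biolink:subclass_of",
         object_category = "biolink:PhenotypicFeature", n = n_isa),
    list(subject_category = "biolink:Protein",
         predicate = "biolink:associated_with",
         object_category = "biolink:Disease", n = length(gd_triples))
  )

  list(
    seed = spec$seed,
    prefix_counts = list(
      CHEBI = length(cp_chem),
      UniProtKB = length(all_proteins),
      HGNC = 0L,  # aliases are normalized away
      MONDO = length(all_diseases),
      HP = length(all_phenotypes)
    ),
    per_source = list(
      drug_target = list(
        nodes = length(cp_chem) + length(unique(drug_target$protein_id)),
        edges = nrow(drug_target)),
      gene_disease = list(
        nodes = length(gd_gene_raw) + length(gd_dis),
        edges = nrow(gene_disease)),
      disease_phenotype = list(
        nodes = length(dp_dis) + length(dp_phe),
        edges = nrow(disease_phenotype)),
      hp_ontology = list(
        nodes = length(phenotypes), edges = n_isa)
    ),
    merged = list(
      node_total = node_total,
      edge_total = edge_total,
      ids_normalized = nrow(id_map),
      edges_deduplicated = spec$n_duplicate_rows,
      dangling_handled = 0L
    ),
    stats = list(
      node_total = node_total,
      edge_total = edge_total,
      nodes_by_category = nodes_by_category,
      edges_by_predicate = list(
        "biolink:associated_with" = length(gd_triples),
        "biolink:has_phenotype" = length(dp_triples),
        "biolink:interacts_with" = length(cp_triples),
        "biolink:subclass_of" = n_isa
      ),
      sankey = sankey
    ),
    ontology = list(
      classes = length(phenotypes) + length(deprecated),
      deprecated = length(deprecated),
      isa_edges = n_isa
    )
  )
}

#' Generate a randomized property graph in memory
#'
#' Draws a small random graph over the miniature model's namespaces —
#' random node sets per prefix, random typed edges between them, optional
#' names with characters that exercise escaping, and multivalued provenance
#' — for property-style testing of serialization, statistics and filtering.
#' Deterministic given the seed.
#'
#' @param seed Integer seed.
#' @param n_nodes,n_edges Approximate graph size.
#' @return A [kg_graph].
#' @export
random_kg_graph <- function(seed = 1L, n_nodes = 20L, n_edges = 30L) {
  model <- kg_mini_model()
  withr::with_seed(seed, {
    prefixes <- sample(c("CHEBI", "UniProtKB", "MONDO", "HP", "HGNC", "GO"),
                       n_nodes, replace = TRUE)
    ids <- unique(sprintf("%s:%07d", prefixes, sample.int(9999999, n_nodes)))
    names_pool <- c("alpha", "beta \"quoted\"", "back\\slash", "plain name",
                    NA_character_)
    nodes <- tibble::tibble(
      id = ids,
      category = purrr::map(ids, function(id) assign_categories(id, model)),
      name = sample(names_pool, length(ids), replace = TRUE),
      provided_by = purrr::map(seq_along(ids), function(i) {
        sample(c("src_a", "src_b"), sample(1:2, 1))
      })
    )
    preds <- names(model$predicates)
    edges <- tibble::tibble(
      subject = sample(ids, n_edges, replace = TRUE),
      predicate = sample(preds, n_edges, replace = TRUE),
      object = sample(ids, n_edges, replace = TRUE),
      knowledge_source = purrr::map(seq_len(n_edges), function(i) {
        sample(c("src_a", "src_b"), sample(1:2, 1))
      })
    )
  })
  kg_graph(nodes, edges)
}
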