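# Shared builders for tests: tiny hand-written graphs and an independent
# hierarchy oracle that re-derives descendant sets from the model file by
# brute-force chain walking (no package hierarchy code involved).

mini <- kg_mini_model()

toy_graph <- function() {
  kg_graph(
    nodes = tibble::tibble(
      id = c("CHEBI:17334", "UniProtKB:P01234", "HGNC:1100", "MONDO:0004335"),
      category = list("biolink:ChemicalEntity", "biolink:Protein",
                      "biolink:Gene", "biolink:Disease"),
      name = c("penicillin", "a protein", "a gene", "digestive disorder"),
      provided_by = list("src_a", "src_a", "src_b", "src_b")
    ),
    edges = tibble::tibble(
      subject = c("CHEBI:17334", "HGNC:1100"),
      predicate = c("biolink:interacts_with", "biolink:associated_with"),
      object = c("UniProtKB:P01234", "MONDO:0004335"),
      knowledge_source = list("src_a", "src_b")
    )
  )
}

# Brute-force descendant oracle: walk every term's parent chain from the raw
# YAML and collect the terms whose chain passes through `term`.
oracle_descendants <- function(term, kind = "categories") {
  y <- yaml::read_yaml(system.file("extdata", "mini-model.yaml",
                                   package = "kgforge"))[[kind]]
  chain <- function(t) {
    out <- t
    while (!is.null(y[[t]])) {
      t <- y[[t]]
      out <- c(out, t)
    }
    out
  }
  names(y)[vapply(names(y), function(t) term %in% chain(t), logical(1))]
}

# Write a small obograph JSON document; classes is a character vector of
# CURIEs, deprecated a subset, isa a two-column data frame (child, parent).
write_toy_obograph <- function(path, classes, deprecated = character(),
                               isa = NULL, iri_base = "http://purl.obolibrary.org/obo/") {
  iri <- function(x) paste0(iri_base, sub(":", "_", x))
  nodes <- lapply(classes, function(cl) {
    n <- list(id = iri(cl), lbl = paste("label", cl), type = "CLASS")
    if (cl %in% deprecated) n$meta <- list(deprecated = TRUE)
    n
  })
  edges <- if (is.null(isa)) list() else {
    unname(Map(function(ch, pa) list(sub = iri(ch), pred = "is_a", obj = iri(pa)),
               isa[[1]], isa[[2]]))
  }
  jsonlite::write_json(
    list(graphs = list(list(nodes = nodes, edges = edges))),
    path, auto_unbox = TRUE, null = "null")
  path
}
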