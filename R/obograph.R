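#' Ingest an obograph JSON ontology as a property graph
#'
#' Reads the obograph serialization used across the OBO Foundry and converts
#' it to a typed property graph. Every ontology class becomes a node: its IRI
#' is contracted to a CURIE via the model's prefix map (kept as a full IRI
#' with a warning when no prefix matches), `lbl` becomes the node name and
#' `meta.definition.val` its description. Node categories are the
#' prefix-assigned categories with `biolink:OntologyClass` inserted before
#' the default, so ontology terms remain recognisable as such while their
#' primary category reflects the namespace (e.g. HP terms are primarily
#' phenotypic features). Classes flagged deprecated are dropped (with a
#' message), along with any edges touching them.
#'
#' `is_a` edges become `biolink:subclass_of` edges. Any other edge keeps its
#' original predicate, contracted to a CURIE, in `relation`, and is typed
#' with the generic `biolink:related_to` — lossless but uniformly typed.
#'
#' @param json_file Path to an obograph JSON document (one or more graphs).
#' @param model A [kg_model] for IRI contraction and category assignment.
#' @return A [kg_graph].
#' @export
read_obograph <- function(json_file, model) {
  stopifnot(is_kg_model(model))
  doc <- jsonlite::fromJSON(json_file, simplifyVector = FALSE)
  graphs <- doc$graphs
  if (is.null(graphs) || length(graphs) == 0) {
    abort(sprintf("%s contains no 'graphs' array", json_file),
          class = "kgforge_format_error")
  }

  nodes_raw <- purrr::flatten(purrr::map(graphs, function(gr) gr$nodes %||% list()))
  edges_raw <- purrr::flatten(purrr::map(graphs, function(gr) gr$edges %||% list()))

  # classes only, where a type is declared
  nodes_raw <- purrr::keep(nodes_raw, function(n) {
    is.null(n$type) || identical(toupper(n$type), "CLASS")
  })

  deprecated <- purrr::map_lgl(nodes_raw, function(n) {
    isTRUE(n$meta$deprecated)
  })
  if (any(deprecated)) {
    dropped_iris <- purrr::map_chr(nodes_raw[deprecated], "id")
    inform(sprintf("Dropping %d deprecated class(es): %s", sum(deprecated),
                   paste(sort_c(dropped_iris), collapse = ", ")))
  } else {
    dropped_iris <- character()
  }
  nodes_raw <- nodes_raw[!deprecated]

  iris <- purrr::map_chr(nodes_raw, "id")
  ids <- contract_iri(iris, model)
  unmatched <- ids == iris & !curie_is_iri_free(ids)
  if (any(unmatched)) {
    warn(sprintf("No prefix matches %d IRI(s); kept as full IRIs: %s",
                 sum(unmatched),
                 paste(sort_c(utils::head(ids[unmatched], 5L)), collapse = ", ")))
  }

  cats <- purrr::map(ids, function(id) ontology_categories(id, model))
  nodes <- tibble::tibble(
    id = ids,
    category = cats,
    name = purrr::map_chr(nodes_raw, function(n) n$lbl %||% NA_character_),
    description = purrr::map_chr(nodes_raw, function(n) {
      n$meta$definition$val %||% NA_character_
    })
  )

  dropped_keys <- c(dropped_iris, contract_iri(dropped_iris, model))
  edges <- purrr::map(edges_raw, function(e) {
    if (e$sub %in% dropped_keys || e$obj %in% dropped_keys) return(NULL)
    subj <- contract_iri(e$sub, model)
    obj <- contract_iri(e$obj, model)
    if (subj %in% dropped_keys || obj %in% dropped_keys) return(NULL)
    if (identical(e$pred, "is_a")) {
      list(subject = subj, predicate = "biolink:subclass_of", object = obj,
           relation = NA_character_)
    } else {
      list(subject = subj, predicate = "biolink:related_to", object = obj,
           relation = contract_iri(e$pred, model))
    }
  })
  edges <- dplyr::bind_rows(purrr::compact(edges))
  kg_graph(nodes, edges)
}

# TRUE where the id does not look like a raw IRI
curie_is_iri_free <- function(x) !grepl("^[A-Za-z][A-Za-z0-9+.-]*://", x)

ontology_categories <- function(id, model) {
  assigned <- if (curie_is_wellformed(id) && curie_is_iri_free(id)) {
    assign_categories(id, model)
  } else {
    model$default_category
  }
  unique(c(setdiff(assigned, model$default_category), "biolink:OntologyClass",
           model$default_category))
}
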