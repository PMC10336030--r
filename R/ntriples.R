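rdf_type_iri <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
rdfs_label_iri <- "http://www.w3.org/2000/01/rdf-schema#label"

# Escape a literal per the n-triples grammar.
nt_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x
}

#' Export a property graph as RDF n-triples
#'
#' Emits, for every node, one `rdf:type` triple per category and one
#' `rdfs:label` triple when the node has a name; and for every edge, one
#' triple relating the expanded subject, predicate and object IRIs. Names
#' are plain literals escaped per the n-triples grammar (no language tags or
#' datatypes). Lines are sorted lexicographically so output is deterministic.
#'
#' Every CURIE prefix appearing in node ids, categories or predicates must be
#' expandable through the model; otherwise an error listing the offending
#' prefixes is raised before anything is written.
#'
#' @param g A [kg_graph].
#' @param model A [kg_model] providing the prefix -> IRI map.
#' @param out_file Path of the n-triples file to write.
#' @return The number of triples written, equal to
#'   `sum over nodes (n categories + has name) + n edges`.
#' @export
write_ntriples <- function(g, model, out_file) {
  stopifnot(is_kg_graph(g), is_kg_model(model))
  curies <- c(
    g$nodes$id,
    unlist(g$nodes$category, use.names = FALSE),
    g$edges$subject, g$edges$predicate, g$edges$object
  )
  curies <- unique(curies[!is.na(curies)])
  not_curie <- !curie_is_wellformed(curies)
  unknown <- union(
    curies[not_curie],
    setdiff(unique(curie_prefix(curies[!not_curie])), names(model$prefixes))
  )
  if (length(unknown) > 0) {
    abort(sprintf("Cannot expand to IRIs (unknown prefix or malformed id): %s",
                  paste(sort_c(unknown), collapse = ", ")),
          class = "kgforge_unmappable_prefix")
  }

  iri <- function(x) paste0("<", expand_curie(x, model), ">")
  lines <- character()

  if (nrow(g$nodes) > 0) {
    type_lines <- purrr::imap(g$nodes$category, function(cats, i) {
      if (length(cats) == 0) return(character(0))
      paste0(iri(g$nodes$id[i]), " <", rdf_type_iri, "> ", iri(cats), " .")
    })
    lines <- c(lines, unlist(type_lines, use.names = FALSE))
    has_name <- !is.na(g$nodes$name)
    if (any(has_name)) {
      lines <- c(lines, paste0(
        iri(g$nodes$id[has_name]), " <", rdfs_label_iri, "> \"",
        nt_escape(g$nodes$name[has_name]), "\" ."
      ))
    }
  }
  if (nrow(g$edges) > 0) {
    lines <- c(lines, paste0(iri(g$edges$subject), " ", iri(g$edges$predicate),
                             " ", iri(g$edges$object), " ."))
  }

  lines <- sort_c(lines)
  writeLines(lines, out_file, useBytes = TRUE)
  length(lines)
}
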