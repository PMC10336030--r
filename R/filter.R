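#' Category-aware subgraph filtering
#'
#' Keeps the edges whose subject and object node categories intersect the
#' transitive descendant sets of the requested categories, and whose
#' predicate lies in the requested predicate's descendant set — so filtering
#' on `biolink:GeneOrGeneProduct` retains nodes typed `biolink:Protein` or
#' `biolink:Gene` (all subcategories are retained). Exactly the nodes
#' incident to a kept edge are kept. The input graph is not modified.
#'
#' `NULL` (or `"any"`) for any of the three slots is a wildcard.
#'
#' @param g A [kg_graph].
#' @param subject_category,object_category Category CURIE or wildcard.
#' @param predicate Predicate CURIE or wildcard.
#' @param model A [kg_model].
#' @return A new [kg_graph] containing the kept edges and their endpoints.
#' @examples
#' \dontrun{
#' filter_graph(g, "biolink:ChemicalEntity", NULL, "biolink:Protein",
#'              kg_mini_model())
#' }
#' @export
filter_graph <- function(g, subject_category = NULL, predicate = NULL,
                         object_category = NULL, model) {
  stopifnot(is_kg_graph(g), is_kg_model(model))
  is_wild <- function(x) is.null(x) || identical(x, "any")

  node_ok <- function(slot) {
    if (is_wild(slot)) return(rep(TRUE, nrow(g$nodes)))
    allowed <- category_descendants(model, slot)
    purrr::map_lgl(g$nodes$category, function(cats) any(cats %in% allowed))
  }
  subj_ok <- stats::setNames(node_ok(subject_category), g$nodes$id)
  obj_ok <- stats::setNames(node_ok(object_category), g$nodes$id)

  pred_ok <- if (is_wild(predicate)) {
    rep(TRUE, nrow(g$edges))
  } else {
    g$edges$predicate %in% predicate_descendants(model, predicate)
  }

  lookup <- function(ok, ids) {
    hit <- unname(ok[ids])
    hit[is.na(hit)] <- FALSE  # dangling endpoints never match
    hit
  }
  keep <- pred_ok &
    lookup(subj_ok, g$edges$subject) &
    lookup(obj_ok, g$edges$object)

  edges <- g$edges[keep, , drop = FALSE]
  incident <- unique(c(edges$subject, edges$object))
  nodes <- g$nodes[g$nodes$id %in% incident, , drop = FALSE]
  kg_graph(nodes, edges)
}
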