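# Multivalued KGX columns represented as list-of-character columns.
kgx_node_list_cols <- c("category", "provided_by", "original_ids")
kgx_edge_list_cols <- c("knowledge_source", "publications")
kgx_node_required <- c("id", "category")
kgx_edge_required <- c("subject", "predicate", "object")
kgx_node_core <- c("id", "category", "name", "description", "provided_by")
kgx_edge_core <- c("subject", "predicate", "object", "relation",
                   "knowledge_source", "publications")

#' Construct a property graph
#'
#' A `kg_graph` is a directed, heterogeneous property graph held as two
#' tibbles: a node table keyed by CURIE `id` and an ordered edge table whose
#' rows each carry a core triple (`subject`, `predicate`, `object`).
#' Multivalued fields (`category`, `provided_by`, `knowledge_source`,
#' `publications`, `original_ids`) are list-of-character columns; any other
#' column is a scalar character property (absent values are `NA`). Extra
#' columns are preserved verbatim through serialization.
#'
#' The constructor normalizes rather than validates: core columns are created
#' when missing, multivalued columns are coerced to list columns, and columns
#' are ordered (required first, then alphabetically) so that two graphs with
#' the same content compare equal. Edges are directed: `(A, p, B)` and
#' `(B, p, A)` are distinct.
#'
#' @param nodes,edges Data frames (or tibbles) of nodes and edges; `NULL`
#'   gives an empty table.
#' @return An object of class `kg_graph`: a list with tibbles `nodes` and
#'   `edges`.
#' @examples
#' g <- kg_graph(
#'   nodes = tibble::tibble(id = c("CHEBI:17334", "UniProtKB:P1"),
#'                          category = c("biolink:ChemicalEntity", "biolink:Protein")),
#'   edges = tibble::tibble(subject = "CHEBI:17334",
#'                          predicate = "biolink:interacts_with",
#'                          object = "UniProtKB:P1")
#' )
#' g
#' @export
kg_graph <- function(nodes = NULL, edges = NULL) {
  structure(
    list(
      nodes = normalize_node_table(nodes),
      edges = normalize_edge_table(edges)
    ),
    class = "kg_graph"
  )
}

normalize_node_table <- function(nodes) {
  nodes <- normalize_table(nodes, kgx_node_core, kgx_node_list_cols)
  order_cols(nodes, kgx_node_required)
}

normalize_edge_table <- function(edges) {
  edges <- normalize_table(edges, kgx_edge_core, kgx_edge_list_cols)
  order_cols(edges, kgx_edge_required)
}

normalize_table <- function(x, core_cols, list_cols) {
  x <- if (is.null(x)) tibble::tibble() else tibble::as_tibble(x)
  for (col in core_cols) {
    if (!col %in% names(x)) {
      x[[col]] <- if (col %in% list_cols) {
        rep(list(character(0)), nrow(x))
      } else {
        rep(NA_character_, nrow(x))
      }
    }
  }
  for (col in names(x)) {
    if (col %in% list_cols) {
      x[[col]] <- as_list_col(x[[col]])
    } else if (is.list(x[[col]])) {
      x[[col]] <- collapse_list_col(x[[col]])
      x[[col]][x[[col]] == ""] <- NA_character_
    } else {
      x[[col]] <- as.character(x[[col]])
      x[[col]][!is.na(x[[col]]) & x[[col]] == ""] <- NA_character_
    }
  }
  x
}

order_cols <- function(x, required) {
  rest <- setdiff(names(x), required)
  x[, c(required, sort_c(rest)), drop = FALSE]
}

#' @rdname kg_graph
#' @param x Object to test.
#' @export
is_kg_graph <- function(x) inherits(x, "kg_graph")

#' @export
print.kg_graph <- function(x, ...) {
  cats <- unique(unlist(purrr::map(x$nodes$category, 1), use.names = FALSE))
  cat(sprintf("<kg_graph> %d nodes, %d edges\n", nrow(x$nodes), nrow(x$edges)))
  if (length(cats) > 0) {
    cat("primary categories:", paste(sort_c(cats), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compare two property graphs on canonical serialization
#'
#' Graphs are equal when their canonically ordered KGX serializations (sorted
#' rows, fixed column order, collapsed list cells) are identical, making the
#' comparison independent of row order and list-column representation.
#'
#' @param a,b `kg_graph` objects.
#' @return `TRUE` or `FALSE`.
#' @export
kg_equal <- function(a, b) {
  identical(kgx_serialize(a), kgx_serialize(b))
}

#' Tidy and summarize property graphs
#'
#' `tidy()` returns the node or edge table; `glance()` a one-row summary.
#'
#' @param x A `kg_graph`.
#' @param what `"nodes"` or `"edges"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.kg_graph <- function(x, what = c("nodes", "edges"), ...) {
  what <- match.arg(what)
  x[[what]]
}

#' @rdname tidy.kg_graph
#' @export
glance.kg_graph <- function(x, ...) {
  tibble::tibble(
    nodes = nrow(x$nodes),
    edges = nrow(x$edges),
    categories = length(unique(unlist(x$nodes$category, use.names = FALSE))),
    predicates = length(unique(x$edges$predicate[!is.na(x$edges$predicate)])),
    sources = length(union(
      unique(unlist(x$nodes$provided_by, use.names = FALSE)),
      unique(unlist(x$edges$knowledge_source, use.names = FALSE))
    ))
  )
}
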