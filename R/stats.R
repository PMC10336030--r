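#' Dashboard-style graph statistics
#'
#' Computes the summary behind a knowledge-graph dashboard: node and edge
#' totals, nodes by primary category, edges by predicate, the category-pair
#' flow table behind a Sankey diagram (subject primary category, predicate,
#' object primary category, count), per-source node/edge counts, and a total
#' degree summary. The primary category is the first listed category, and
#' Sankey counts use primary categories only, so all three conservation sums
#' hold exactly: nodes by category sum to the node total, and both the
#' predicate and Sankey tallies sum to the edge total. A node or edge is
#' attributed to every source in its provenance list, so `by_source` counts
#' may sum to more than the totals.
#'
#' @param g A [kg_graph] with no dangling edges (merge or validate first).
#' @return An object of class `kg_stats`.
#' @export
compute_stats <- function(g) {
  stopifnot(is_kg_graph(g))
  primary <- purrr::map_chr(g$nodes$category, function(cats) {
    if (length(cats) == 0) NA_character_ else cats[1]
  })
  names(primary) <- g$nodes$id

  dangling <- setdiff(unique(c(g$edges$subject, g$edges$object)), g$nodes$id)
  if (length(dangling) > 0) {
    abort(sprintf(
      "Graph has %d dangling endpoint(s) (e.g. %s); merge or validate before computing statistics",
      length(dangling), dangling[1]), class = "kgforge_stats_error")
  }

  nodes_by_category <- tibble::tibble(category = unname(primary)) %>%
    dplyr::count(.data$category, name = "n") %>%
    dplyr::arrange(.data$category)

  edges_by_predicate <- tibble::tibble(predicate = g$edges$predicate) %>%
    dplyr::count(.data$predicate, name = "n") %>%
    dplyr::arrange(.data$predicate)

  sankey <- tibble::tibble(
    subject_category = unname(primary[g$edges$subject]),
    predicate = g$edges$predicate,
    object_category = unname(primary[g$edges$object])
  ) %>%
    dplyr::count(.data$subject_category, .data$predicate,
                 .data$object_category, name = "n") %>%
    dplyr::arrange(.data$subject_category, .data$predicate,
                   .data$object_category)

  node_sources <- tibble::tibble(
    source = as.character(unlist(g$nodes$provided_by, use.names = FALSE))
  ) %>% dplyr::count(.data$source, name = "nodes")
  edge_sources <- tibble::tibble(
    source = as.character(unlist(g$edges$knowledge_source, use.names = FALSE))
  ) %>% dplyr::count(.data$source, name = "edges")
  by_source <- dplyr::full_join(node_sources, edge_sources, by = "source") %>%
    dplyr::mutate(nodes = dplyr::coalesce(.data$nodes, 0L),
                  edges = dplyr::coalesce(.data$edges, 0L)) %>%
    dplyr::arrange(.data$source)

  deg <- table(factor(c(g$edges$subject, g$edges$object), levels = g$nodes$id))
  degree_summary <- if (nrow(g$nodes) == 0) {
    list(min = 0L, median = 0, max = 0L)
  } else {
    list(min = as.integer(min(deg)), median = as.numeric(stats::median(deg)),
         max = as.integer(max(deg)))
  }

  structure(list(
    node_total = nrow(g$nodes),
    edge_total = nrow(g$edges),
    nodes_by_category = nodes_by_category,
    edges_by_predicate = edges_by_predicate,
    sankey = sankey,
    by_source = by_source,
    degree_summary = degree_summary
  ), class = "kg_stats")
}

#' @export
print.kg_stats <- function(x, ...) {
  cat(sprintf("<kg_stats> %d nodes, %d edges\n", x$node_total, x$edge_total))
  cat(sprintf("categories: %d | predicates: %d | category pairs: %d | sources: %d\n",
              nrow(x$nodes_by_category), nrow(x$edges_by_predicate),
              nrow(x$sankey), nrow(x$by_source)))
  invisible(x)
}

#' Tidy and summarize graph statistics
#'
#' `tidy()` returns one of the count tables; `glance()` a one-row overview.
#'
#' @param x A `kg_stats` object.
#' @param what Which table: `"sankey"`, `"categories"`, `"predicates"` or
#'   `"sources"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.kg_stats <- function(x, what = c("sankey", "categories", "predicates",
                                      "sources"), ...) {
  what <- match.arg(what)
  switch(what,
         sankey = x$sankey,
         categories = x$nodes_by_category,
         predicates = x$edges_by_predicate,
         sources = x$by_source)
}

#' @rdname tidy.kg_stats
#' @export
glance.kg_stats <- function(x, ...) {
  tibble::tibble(
    node_total = x$node_total,
    edge_total = x$edge_total,
    n_categories = nrow(x$nodes_by_category),
    n_predicates = nrow(x$edges_by_predicate),
    n_category_pairs = nrow(x$sankey),
    n_sources = nrow(x$by_source),
    degree_min = x$degree_summary$min,
    degree_median = x$degree_summary$median,
    degree_max = x$degree_summary$max
  )
}

#' Plot graph statistics
#'
#' Bar charts of the dashboard tallies: category-pair flows (default),
#' nodes by primary category, or edges by predicate.
#'
#' @param object A `kg_stats` object.
#' @param type `"sankey"`, `"categories"` or `"predicates"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kg_stats <- function(object, type = c("sankey", "categories",
                                               "predicates"), ...) {
  type <- match.arg(type)
  strip <- function(x) sub("^biolink:", "", x)
  if (type == "sankey") {
    d <- object$sankey %>%
      dplyr::mutate(flow = paste0(strip(.data$subject_category), " —",
                                  strip(.data$predicate), "→ ",
                                  strip(.data$object_category)))
    ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$flow, .data$n),
                                    y = .data$n)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "edges",
                    title = "Category-pair flows") +
      ggplot2::theme_minimal()
  } else if (type == "categories") {
    d <- dplyr::mutate(object$nodes_by_category,
                       category = strip(.data$category))
    ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$category, .data$n),
                                    y = .data$n)) +
      ggplot2::geom_col(fill = "darkseagreen4") +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "nodes", title = "Nodes by primary category") +
      ggplot2::theme_minimal()
  } else {
    d <- dplyr::mutate(object$edges_by_predicate,
                       predicate = strip(.data$predicate))
    ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$predicate, .data$n),
                                    y = .data$n)) +
      ggplot2::geom_col(fill = "sienna3") +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "edges", title = "Edges by predicate") +
      ggplot2::theme_minimal()
  }
}

#' Write graph statistics
#'
#' Writes `stats.json` (stable schema) and `sankey.tsv` (the category-pair
#' flow table).
#'
#' @param stats A `kg_stats` object.
#' @param out_dir Directory to write into.
#' @return Paths written, invisibly.
#' @export
write_stats <- function(stats, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  json <- file.path(out_dir, "stats.json")
  tsv <- file.path(out_dir, "sankey.tsv")
  write_json_file(list(
    node_total = stats$node_total,
    edge_total = stats$edge_total,
    nodes_by_category = stats::setNames(as.list(stats$nodes_by_category$n),
                                        stats$nodes_by_category$category),
    edges_by_predicate = stats::setNames(as.list(stats$edges_by_predicate$n),
                                         stats$edges_by_predicate$predicate),
    sankey = purrr::pmap(stats$sankey,
      function(subject_category, predicate, object_category, n) {
        list(subject_category = subject_category, predicate = predicate,
             object_category = object_category, n = n)
      }),
    by_source = purrr::pmap(stats$by_source, function(source, nodes, edges) {
      list(source = source, nodes = nodes, edges = edges)
    }),
    degree_summary = stats$degree_summary
  ), json)
  readr::write_tsv(stats$sankey, tsv, quote = "none", escape = "none")
  invisible(c(json, tsv))
}
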