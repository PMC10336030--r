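#' Close an alias -> canonical identifier map
#'
#' Resolves alias chains (`A -> B`, `B -> C` becomes `A -> C`, `B -> C`) so
#' every alias points at its terminal canonical id. A cyclic map is a
#' configuration error.
#'
#' @param id_map A two-column data frame (`alias`, `canonical`) or a named
#'   character vector (names = aliases).
#' @return Named character vector: alias -> terminal canonical id.
#' @export
close_id_map <- function(id_map) {
  if (is.data.frame(id_map)) {
    id_map <- stats::setNames(as.character(id_map[[2]]),
                              as.character(id_map[[1]]))
  }
  if (length(id_map) == 0) return(stats::setNames(character(), character()))
  out <- id_map
  for (alias in names(out)) {
    seen <- alias
    cur <- out[[alias]]
    while (cur %in% names(id_map)) {
      if (cur %in% seen) {
        abort(sprintf("Cyclic id map: %s",
                      paste(c(seen, cur), collapse = " -> ")),
              class = "kgforge_config_error")
      }
      seen <- c(seen, cur)
      cur <- id_map[[cur]]
    }
    out[[alias]] <- cur
  }
  out
}

#' Rewrite identifiers through an alias map
#'
#' Every node id and edge endpoint is rewritten through the closed alias ->
#' canonical map. A rewritten node records its previous id in the
#' multivalued `original_ids` property; when an alias node and its canonical
#' node both exist they are reconciled with [resolve_node_conflicts()] and
#' `original_ids` lists both identifiers.
#'
#' @param g A [kg_graph].
#' @param id_map Alias map accepted by [close_id_map()].
#' @param model Optional [kg_model] used to re-sort reconciled categories.
#' @return A [kg_graph] with canonical identifiers.
#' @export
normalize_ids <- function(g, id_map, model = NULL) {
  stopifnot(is_kg_graph(g))
  map <- close_id_map(id_map)
  if (length(map) == 0) return(g)
  rewrite <- function(x) {
    hit <- x %in% names(map)
    x[hit] <- unname(map[x[hit]])
    x
  }
  nodes <- g$nodes
  hit <- nodes$id %in% names(map)
  if (any(hit)) {
    nodes$original_ids <- purrr::map2(
      nodes[["original_ids"]] %||% rep(list(character(0)), nrow(nodes)),
      seq_len(nrow(nodes)),
      function(orig, i) {
        if (hit[i]) union_keep_order(orig, nodes$id[i]) else orig
      }
    )
    # a node colliding with a rewritten alias contributes its own id too
    new_ids <- rewrite(nodes$id)
    collided <- new_ids %in% new_ids[hit] & !hit & duplicated_any(new_ids)
    nodes$original_ids <- purrr::map2(nodes$original_ids, seq_len(nrow(nodes)),
      function(orig, i) {
        if (collided[i]) union_keep_order(orig, nodes$id[i]) else orig
      })
    nodes$id <- new_ids
  }
  dedup <- dedup_nodes(nodes, model)
  for (w in dedup$conflicts) warn(w)
  edges <- g$edges
  edges$subject <- rewrite(edges$subject)
  edges$object <- rewrite(edges$object)
  kg_graph(dedup$nodes, edges)
}

duplicated_any <- function(x) duplicated(x) | duplicated(x, fromLast = TRUE)

#' Reconcile two nodes with the same identifier
#'
#' Scalar fields take the first non-empty value in input order; when both
#' are non-empty and differ, the first wins and a conflict is reported as a
#' warning. List fields (categories, provenance, multivalued properties) are
#' unioned preserving order of first appearance; when a model is supplied,
#' categories are re-sorted most specific first by hierarchy depth.
#'
#' @param a,b One-row node tibbles (or data frames) with `a$id == b$id`.
#' @param model Optional [kg_model].
#' @return A one-row node tibble.
#' @export
resolve_node_conflicts <- function(a, b, model = NULL) {
  a <- normalize_node_table(a)
  b <- normalize_node_table(b)
  stopifnot(nrow(a) == 1, nrow(b) == 1, identical(a$id, b$id))
  dedup <- dedup_nodes(dplyr::bind_rows(a, b), model)
  for (w in dedup$conflicts) warn(w)
  dedup$nodes
}

#' Read a merge configuration
#'
#' `merge.yaml` lists the subgraphs to combine (`inputs`: KGX directories or
#' bare source names resolved against a build's `transformed/` directory, in
#' conflict-resolution priority order), an optional two-column `id_map` TSV
#' (alias, canonical), the dangling-endpoint policy `on_dangling`
#' (`stub`, `drop` or `error`; default `stub`) and an `output` directory
#' name.
#'
#' @param path Path to a merge YAML file.
#' @return A list of class `kg_merge_config`.
#' @export
read_merge_config <- function(path) {
  y <- read_yaml_file(path)
  if (is.null(y$inputs) || length(y$inputs) == 0) {
    abort(sprintf("%s: merge config needs a non-empty 'inputs' list", path),
          class = "kgforge_config_error")
  }
  y$on_dangling <- y$on_dangling %||% "stub"
  if (!y$on_dangling %in% c("stub", "drop", "error")) {
    abort(sprintf("%s: on_dangling must be stub, drop or error", path),
          class = "kgforge_config_error")
  }
  y$output <- y$output %||% "merged"
  y$config_dir <- dirname(path)
  structure(y, class = "kg_merge_config")
}

read_id_map <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE, show_col_types = FALSE)
  if (ncol(x) < 2) {
    abort(sprintf("%s: id map needs two columns (alias, canonical)", path),
          class = "kgforge_config_error")
  }
  x[, 1:2]
}

#' Merge transformed subgraphs into one graph
#'
#' The KGX-style merge: identifiers are normalized through the (closed)
#' alias map, the node set is the union over canonical ids with conflicts
#' resolved in input order (input order is the priority order), and edges
#' are deduplicated on the core-triple key `(subject, predicate, object,
#' relation)` with `knowledge_source` and `publications` unioned across
#' duplicates. Edge endpoints with no node are handled per `on_dangling`:
#' `"stub"` (default) creates a typed stub node `provided_by = ["stub"]`,
#' `"drop"` removes the edge, `"error"` fails listing the endpoints. Output
#' is deterministic.
#'
#' @param inputs A list of [kg_graph] objects and/or paths to KGX
#'   directories, optionally named (names become source labels in the
#'   report; unnamed directory inputs use the directory name).
#' @param model A [kg_model].
#' @param id_map Optional alias map ([close_id_map()] input) or path to a
#'   two-column TSV.
#' @param on_dangling One of `"stub"`, `"drop"`, `"error"`.
#' @return A list of class `kg_merge_result`: `graph` (a [kg_graph]) and
#'   `report` (per-source counts, `nodes_merged`, `edges_deduplicated`,
#'   `ids_normalized`, `dangling_handled`).
#' @export
merge_graphs <- function(inputs, model, id_map = NULL,
                         on_dangling = c("stub", "drop", "error")) {
  on_dangling <- match.arg(on_dangling)
  stopifnot(is_kg_model(model))
  if (is_kg_graph(inputs)) inputs <- list(inputs)

  given <- names(inputs) %||% rep("", length(inputs))
  graphs <- purrr::map(inputs, function(inp) {
    if (is_kg_graph(inp)) inp else read_kgx_dir(inp)
  })
  labels <- purrr::map_chr(seq_along(inputs), function(i) {
    if (nzchar(given[i])) given[i]
    else if (is.character(inputs[[i]])) basename(inputs[[i]])
    else sprintf("input_%d", i)
  })

  map <- if (is.null(id_map)) {
    stats::setNames(character(), character())
  } else if (is.character(id_map) && is.null(names(id_map)) &&
             length(id_map) == 1) {
    if (!file.exists(id_map)) {
      abort(sprintf("Id map file not found: %s", id_map),
            class = "kgforge_io_error")
    }
    close_id_map(read_id_map(id_map))
  } else {
    close_id_map(id_map)
  }

  ids_before <- purrr::map(graphs, function(g) g$nodes$id)
  normalized <- purrr::map(graphs, function(g) {
    suppressWarnings(normalize_ids(g, map, model))
  })
  ids_normalized <- length(unique(unlist(purrr::map2(
    ids_before, normalized,
    function(before, g) intersect(before, names(map))
  ), use.names = FALSE)))

  per_source <- tibble::tibble(
    source = labels,
    nodes = purrr::map_int(normalized, function(g) nrow(g$nodes)),
    edges = purrr::map_int(normalized, function(g) nrow(g$edges))
  )

  id_sets <- purrr::map(normalized, function(g) unique(g$nodes$id))
  id_occurrences <- table(unlist(id_sets, use.names = FALSE))
  nodes_merged <- sum(id_occurrences > 1)

  all_nodes <- dplyr::bind_rows(purrr::map(normalized, "nodes"))
  dedup <- dedup_nodes(all_nodes, model)
  conflicts <- dedup$conflicts
  nodes <- dedup$nodes

  all_edges <- normalize_edge_table(
    dplyr::bind_rows(purrr::map(normalized, "edges")))
  edges <- dedup_edges(all_edges)
  edges_deduplicated <- nrow(all_edges) - nrow(edges)

  endpoints <- unique(c(edges$subject, edges$object))
  dangling <- setdiff(endpoints, nodes$id)
  if (length(dangling) > 0) {
    if (on_dangling == "error") {
      abort(sprintf("Dangling edge endpoint(s): %s",
                    paste(sort_c(dangling), collapse = ", ")),
            class = "kgforge_merge_error")
    } else if (on_dangling == "drop") {
      edges <- edges[edges$subject %in% nodes$id & edges$object %in% nodes$id, ,
                     drop = FALSE]
    } else {
      warn(sprintf("Created %d stub node(s) for dangling endpoint(s): %s",
                   length(dangling), paste(sort_c(dangling), collapse = ", ")))
      stubs <- tibble::tibble(
        id = sort_c(dangling),
        category = purrr::map(sort_c(dangling), function(id) {
          if (curie_is_wellformed(id)) assign_categories(id, model)
          else model$default_category
        }),
        provided_by = rep(list("stub"), length(dangling))
      )
      nodes <- dplyr::bind_rows(nodes, normalize_node_table(stubs))
    }
  }

  graph <- kg_graph(nodes, edges)
  report <- structure(list(
    sources = per_source,
    nodes_merged = nodes_merged,
    edges_deduplicated = edges_deduplicated,
    ids_normalized = ids_normalized,
    dangling_handled = length(dangling),
    dangling_action = on_dangling,
    node_total = nrow(graph$nodes),
    edge_total = nrow(graph$edges),
    conflicts = as.list(conflicts)
  ), class = "kg_merge_report")
  structure(list(graph = graph, report = report), class = "kg_merge_result")
}

# Deduplicate edges on (subject, predicate, object, relation); list-valued
# provenance unioned across duplicates, scalars first-seen-wins.
dedup_edges <- function(edges) {
  if (nrow(edges) == 0) return(edges)
  key <- paste(edges$subject, edges$predicate, edges$object,
               ifelse(is.na(edges$relation), "", edges$relation), sep = "\r")
  groups <- split(seq_len(nrow(edges)), key)
  groups <- groups[unique(key)]
  merged <- purrr::map(groups, function(idx) {
    if (length(idx) == 1) return(edges[idx, , drop = FALSE])
    out <- edges[idx[1], , drop = FALSE]
    for (col in names(edges)) {
      vals <- edges[[col]][idx]
      if (is.list(edges[[col]])) {
        out[[col]] <- list(union_keep_order(unlist(vals, use.names = FALSE)))
      } else {
        out[[col]] <- first_non_empty(vals)
      }
    }
    out
  })
  dplyr::bind_rows(merged)
}

#' Run a merge from a configuration file
#'
#' Resolves the config's inputs (bare names against `transformed_dir`, paths
#' against the config directory), merges, and — when `out_dir` is given —
#' writes the merged KGX pair plus `merge_report.json`.
#'
#' @param config A [read_merge_config()] result or path.
#' @param model A [kg_model].
#' @param transformed_dir Directory holding `transformed/<SOURCE>/` inputs.
#' @param raw_dir Directory holding downloaded artifacts (a bare `id_map`
#'   file name resolves here first, so builds are self-contained).
#' @param out_dir Optional output directory.
#' @return A `kg_merge_result` (invisibly when writing).
#' @export
run_merge <- function(config, model, transformed_dir = NULL, raw_dir = NULL,
                      out_dir = NULL) {
  if (is.character(config)) config <- read_merge_config(config)
  stopifnot(inherits(config, "kg_merge_config"))
  resolve_input <- function(inp) {
    if (dir.exists(inp)) return(inp)
    if (!is.null(transformed_dir) && dir.exists(file.path(transformed_dir, inp))) {
      return(file.path(transformed_dir, inp))
    }
    cand <- file.path(config$config_dir, inp)
    if (dir.exists(cand)) return(cand)
    abort(sprintf("Merge input not found: %s", inp), class = "kgforge_io_error")
  }
  paths <- purrr::map_chr(config$inputs, resolve_input)
  names(paths) <- purrr::map_chr(config$inputs, basename)
  id_map <- config$id_map
  if (!is.null(id_map) && !file.exists(id_map)) {
    candidates <- c(
      if (!is.null(raw_dir)) file.path(raw_dir, config$id_map),
      file.path(config$config_dir, config$id_map)
    )
    hit <- candidates[file.exists(candidates)]
    id_map <- if (length(hit) > 0) hit[1] else candidates[length(candidates)]
  }
  res <- merge_graphs(as.list(paths), model, id_map = id_map,
                      on_dangling = config$on_dangling)
  if (!is.null(out_dir)) {
    write_kgx(res$graph, out_dir)
    write_merge_report(res$report, file.path(out_dir, "merge_report.json"))
    return(invisible(res))
  }
  res
}

#' Serialize a merge report as JSON
#'
#' @param report A `kg_merge_report`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_merge_report <- function(report, path) {
  out <- list(
    sources = purrr::pmap(report$sources, function(source, nodes, edges) {
      list(source = source, nodes = nodes, edges = edges)
    }),
    nodes_merged = report$nodes_merged,
    edges_deduplicated = report$edges_deduplicated,
    ids_normalized = report$ids_normalized,
    dangling_handled = report$dangling_handled,
    dangling_action = report$dangling_action,
    node_total = report$node_total,
    edge_total = report$edge_total,
    conflicts = report$conflicts
  )
  write_json_file(out, path)
}

#' @export
print.kg_merge_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<kg_merge_result> %d nodes, %d edges from %d source(s)\n",
    r$node_total, r$edge_total, nrow(r$sources)))
  cat(sprintf(
    "  nodes merged: %d | edges deduplicated: %d | ids normalized: %d | dangling: %d (%s)\n",
    r$nodes_merged, r$edges_deduplicated, r$ids_normalized,
    r$dangling_handled, r$dangling_action))
  invisible(x)
}

#' Tidy and summarize merge results
#'
#' `tidy()` returns the per-source count table, `glance()` the one-row merge
#' summary.
#'
#' @param x A `kg_merge_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.kg_merge_result <- function(x, ...) x$report$sources

#' @rdname tidy.kg_merge_result
#' @export
glance.kg_merge_result <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    node_total = r$node_total, edge_total = r$edge_total,
    nodes_merged = r$nodes_merged, edges_deduplicated = r$edges_deduplicated,
    ids_normalized = r$ids_normalized, dangling_handled = r$dangling_handled
  )
}
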