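filter_ops <- c("eq", "ne", "lt", "le", "gt", "ge", "in", "not_in")

#' Read a declarative transform configuration
#'
#' A transform config maps one tabular (or obograph) source to a typed
#' subgraph without any per-source code. Keys: `source_name`, `input_file`,
#' `format` (`tsv`, `csv`, `jsonl` or `obograph`), optional `delimiter`,
#' `filters` (list of `{column, op, value}` with ops
#' `eq, ne, lt, le, gt, ge, in, not_in`), `nodes` (list of node rules:
#' `id_column`, optional `prefix`, `category`, `name_column`, `properties`
#' map column -> property) and `edges` (list of edge rules: `subject_column`
#' / `object_column` with optional prefixes, `predicate` fixed CURIE or
#' `predicate_column` with optional `predicate_map`, `properties`).
#'
#' @param path Path to a transform YAML file.
#' @return A list of class `kg_transform_config`.
#' @export
read_transform_config <- function(path) {
  y <- read_yaml_file(path)
  if (is.null(y$source_name) || !nzchar(y$source_name)) {
    abort(sprintf("%s: source_name is required and non-empty", path),
          class = "kgforge_config_error")
  }
  if (is.null(y$input_file)) {
    abort(sprintf("%s: input_file is required", path),
          class = "kgforge_config_error")
  }
  y$format <- y$format %||% "tsv"
  if (!y$format %in% c("tsv", "csv", "jsonl", "obograph")) {
    abort(sprintf("%s: unknown format '%s'", path, y$format),
          class = "kgforge_config_error")
  }
  y$filters <- y$filters %||% list()
  for (f in y$filters) {
    if (is.null(f$column) || is.null(f$op) || is.null(f$value) ||
        !f$op %in% filter_ops) {
      abort(sprintf("%s: each filter needs column, op (one of %s) and value",
                    path, paste(filter_ops, collapse = ", ")),
            class = "kgforge_config_error")
    }
  }
  y$nodes <- y$nodes %||% list()
  y$edges <- y$edges %||% list()
  y$config_dir <- dirname(path)
  structure(y, class = "kg_transform_config")
}

#' Row filters for declarative transforms
#'
#' Applies the conjunction of all filter rules to each row of a table. The
#' comparison operators `lt`, `le`, `gt`, `ge` coerce the column (and the
#' rule value) to numeric first; a row whose cell cannot be coerced is
#' dropped with a warning recorded. `eq`/`ne` compare as strings;
#' `in`/`not_in` test membership in the rule's value list. An empty filter
#' list keeps every row.
#'
#' @param data A data frame of rows (all columns character is fine).
#' @param filters List of filter rules (`column`, `op`, `value`).
#' @return A list with `keep` (logical vector over rows) and `warnings`
#'   (character vector describing coercion failures).
#' @export
apply_filters <- function(data, filters) {
  keep <- rep(TRUE, nrow(data))
  warnings <- character()
  for (f in filters) {
    if (!f$column %in% names(data)) {
      abort(sprintf("Filter references missing column '%s'", f$column),
            class = "kgforge_config_error")
    }
    col <- as.character(data[[f$column]])
    vals <- as.character(unlist(f$value))
    hit <- switch(
      f$op,
      eq = col == vals[1],
      ne = col != vals[1],
      "in" = col %in% vals,
      not_in = !(col %in% vals),
      {
        num <- suppressWarnings(as.numeric(col))
        ref <- suppressWarnings(as.numeric(vals[1]))
        if (is.na(ref)) {
          abort(sprintf("Filter value '%s' for op '%s' is not numeric",
                        vals[1], f$op), class = "kgforge_config_error")
        }
        failed <- is.na(num) & !is.na(col)
        if (any(failed)) {
          warnings <- c(warnings, sprintf(
            "column '%s': %d row(s) dropped, value not numeric (e.g. '%s')",
            f$column, sum(failed), col[which(failed)[1]]))
        }
        out <- switch(f$op,
                      lt = num < ref, le = num <= ref,
                      gt = num > ref, ge = num >= ref)
        out[is.na(out)] <- FALSE
        out
      }
    )
    hit[is.na(hit)] <- FALSE
    keep <- keep & hit
  }
  list(keep = keep, warnings = warnings)
}

read_source_table <- function(path, format, delimiter = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("Input file not found: %s", path), class = "kgforge_io_error")
  }
  if (format == "jsonl") {
    rows <- purrr::map(readLines(path, warn = FALSE), function(l) {
      purrr::map(jsonlite::fromJSON(l), as.character)
    })
    return(dplyr::bind_rows(rows))
  }
  delim <- delimiter %||% if (format == "csv") "," else "\t"
  readr::read_delim(path, delim = delim, quote = "\"",
                    col_types = readr::cols(.default = readr::col_character()),
                    na = "", progress = FALSE, show_col_types = FALSE,
                    lazy = FALSE)
}

#' Transform one source into a typed subgraph
#'
#' Runs the declarative transform: reads the input table, applies filters,
#' then materializes nodes and edges per the config's rules. Every node is
#' stamped `provided_by = [source_name]` and typed via the rule's category
#' override (plus its ancestors) or [assign_categories()]; every edge is
#' stamped `knowledge_source = [source_name]`. Duplicate node ids within the
#' source are merged first-seen-wins for scalars (conflicts recorded as
#' warnings) with list properties unioned. A row that produces a malformed
#' CURIE is skipped and counted in `rows_errored`.
#'
#' For `format: obograph` the input is delegated to [read_obograph()] and
#' provenance-stamped the same way.
#'
#' @param config A [read_transform_config()] result or path to one.
#' @param model A [kg_model].
#' @param input_dir Optional directory against which a relative `input_file`
#'   is resolved (defaults to the config file's directory).
#' @return A list of class `kg_transform_result`: `graph` (a [kg_graph]) and
#'   `report` (rows_read, rows_filtered, rows_errored, rows_transformed,
#'   nodes, edges, warnings).
#' @export
transform_source <- function(config, model, input_dir = NULL) {
  if (is.character(config)) config <- read_transform_config(config)
  stopifnot(inherits(config, "kg_transform_config"), is_kg_model(model))
  input <- config$input_file
  if (!file.exists(input)) {
    base <- input_dir %||% config$config_dir %||% "."
    input <- file.path(base, config$input_file)
  }

  if (config$format == "obograph") {
    return(transform_obograph(config, model, input))
  }

  data <- read_source_table(input, config$format, config$delimiter)
  referenced <- unique(unlist(c(
    purrr::map(config$filters, "column"),
    purrr::map(config$nodes, function(r) {
      c(r$id_column, r$name_column, unlist(r$properties, use.names = FALSE))
    }),
    purrr::map(config$edges, function(r) {
      c(r$subject_column, r$object_column, r$predicate_column,
        unlist(r$properties, use.names = FALSE))
    })
  )))
  missing <- setdiff(referenced, names(data))
  if (length(missing) > 0) {
    abort(sprintf("Transform '%s' references column(s) absent from %s: %s",
                  config$source_name, input, paste(missing, collapse = ", ")),
          class = "kgforge_config_error")
  }

  flt <- apply_filters(data, config$filters)
  kept <- data[flt$keep, , drop = FALSE]
  warnings <- flt$warnings

  # validate produced CURIEs row-wise; a bad row is skipped entirely
  apply_prefix <- function(values, prefix) {
    if (is.null(prefix)) values else paste0(prefix, values)
  }
  row_ids <- purrr::map(seq_len(nrow(kept)), function(i) {
    unlist(c(
      purrr::map(config$nodes, function(r) {
        apply_prefix(kept[[r$id_column]][i], r$prefix)
      }),
      purrr::map(config$edges, function(r) {
        c(apply_prefix(kept[[r$subject_column]][i], r$subject_prefix),
          apply_prefix(kept[[r$object_column]][i], r$object_prefix))
      })
    ))
  })
  row_ok <- purrr::map_lgl(row_ids, function(ids) all(curie_is_wellformed(ids)))
  if (any(!row_ok)) {
    bad_ids <- unlist(purrr::map(row_ids[!row_ok], function(ids) {
      ids[!curie_is_wellformed(ids)]
    }))
    warnings <- c(warnings, sprintf(
      "%d row(s) skipped: malformed CURIE(s) %s", sum(!row_ok),
      paste(sprintf("'%s'", utils::head(unique(bad_ids), 5L)), collapse = ", ")))
  }
  rows <- kept[row_ok, , drop = FALSE]

  nodes <- purrr::map(config$nodes, function(r) {
    ids <- apply_prefix(rows[[r$id_column]], r$prefix)
    cats <- if (!is.null(r$category)) {
      cat_list <- unique(c(r$category,
                           term_ancestors(model$categories, r$category),
                           model$default_category))
      rep(list(cat_list), length(ids))
    } else {
      purrr::map(ids, function(id) assign_categories(id, model))
    }
    out <- tibble::tibble(id = ids, category = cats,
                          provided_by = rep(list(config$source_name), length(ids)))
    if (!is.null(r$name_column)) out$name <- rows[[r$name_column]]
    for (col in names(r$properties %||% list())) {
      out[[r$properties[[col]]]] <- rows[[col]]
    }
    out
  })
  nodes <- dplyr::bind_rows(nodes)
  dedup <- dedup_nodes(nodes, model)
  warnings <- c(warnings, dedup$conflicts)
  edges <- purrr::map(config$edges, function(r) {
    if (nrow(rows) == 0) return(NULL)
    pred <- if (!is.null(r$predicate_column)) {
      raw <- rows[[r$predicate_column]]
      if (!is.null(r$predicate_map)) {
        mapped <- unlist(r$predicate_map)[raw]
        ifelse(is.na(mapped), raw, unname(mapped))
      } else raw
    } else {
      rep(r$predicate, nrow(rows))
    }
    out <- tibble::tibble(
      subject = apply_prefix(rows[[r$subject_column]], r$subject_prefix),
      predicate = pred,
      object = apply_prefix(rows[[r$object_column]], r$object_prefix),
      knowledge_source = rep(list(config$source_name), nrow(rows))
    )
    if (!is.null(r$relation)) out$relation <- r$relation
    for (col in names(r$properties %||% list())) {
      out[[r$properties[[col]]]] <- rows[[col]]
    }
    out
  })
  edges <- dplyr::bind_rows(purrr::compact(edges))

  graph <- kg_graph(dedup$nodes, edges)
  report <- list(
    source_name = config$source_name,
    rows_read = nrow(data),
    rows_filtered = sum(!flt$keep),
    rows_errored = sum(!row_ok),
    rows_transformed = nrow(rows),
    nodes = nrow(graph$nodes),
    edges = nrow(graph$edges),
    warnings = as.list(warnings)
  )
  structure(list(graph = graph, report = report),
            class = "kg_transform_result")
}

transform_obograph <- function(config, model, input) {
  n_dropped <- 0L
  withCallingHandlers(
    graph <- read_obograph(input, model),
    message = function(m) {
      hit <- regmatches(conditionMessage(m),
                        regexec("Dropping ([0-9]+) deprecated",
                                conditionMessage(m)))[[1]]
      if (length(hit) == 2) n_dropped <<- as.integer(hit[2])
      invokeRestart("muffleMessage")
    }
  )
  graph$nodes$provided_by <- rep(list(config$source_name), nrow(graph$nodes))
  graph$edges$knowledge_source <- rep(list(config$source_name), nrow(graph$edges))
  graph <- kg_graph(graph$nodes, graph$edges)
  report <- list(
    source_name = config$source_name,
    rows_read = nrow(graph$nodes) + n_dropped,
    rows_filtered = n_dropped,
    rows_errored = 0L,
    rows_transformed = nrow(graph$nodes),
    nodes = nrow(graph$nodes),
    edges = nrow(graph$edges),
    warnings = list()
  )
  structure(list(graph = graph, report = report),
            class = "kg_transform_result")
}

# First-seen-wins node dedup; list columns unioned; scalar conflicts logged.
dedup_nodes <- function(nodes, model = NULL) {
  if (nrow(nodes) == 0) {
    return(list(nodes = nodes, conflicts = character()))
  }
  nodes <- normalize_node_table(nodes)
  conflicts <- character()
  groups <- split(seq_len(nrow(nodes)), nodes$id)
  groups <- groups[unique(nodes$id)]  # keep first-seen order
  merged <- purrr::map(groups, function(idx) {
    if (length(idx) == 1) return(nodes[idx, , drop = FALSE])
    out <- nodes[idx[1], , drop = FALSE]
    for (col in names(nodes)) {
      vals <- nodes[[col]][idx]
      if (is.list(nodes[[col]])) {
        out[[col]] <- list(union_keep_order(unlist(vals, use.names = FALSE)))
      } else {
        non_empty <- vals[!is_empty_scalar(vals)]
        if (length(unique(non_empty)) > 1) {
          conflicts <<- c(conflicts, sprintf(
            "node %s: conflicting '%s' values (%s); kept first",
            nodes$id[idx[1]], col,
            paste(sprintf("'%s'", unique(non_empty)), collapse = " vs ")))
        }
        out[[col]] <- first_non_empty(vals)
      }
    }
    out
  })
  merged <- dplyr::bind_rows(merged)
  if (!is.null(model)) {
    merged$category <- purrr::map(merged$category, sort_categories_by_depth,
                                  model = model)
  }
  list(nodes = merged, conflicts = conflicts)
}

#' @export
print.kg_transform_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<kg_transform_result> %s: %d rows -> %d nodes, %d edges (%d filtered, %d errored)\n",
    r$source_name, r$rows_read, r$nodes, r$edges, r$rows_filtered,
    r$rows_errored))
  invisible(x)
}

#' @rdname transform_source
#' @param x A `kg_transform_result`.
#' @param ... Unused.
#' @export
glance.kg_transform_result <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    source_name = r$source_name, rows_read = r$rows_read,
    rows_filtered = r$rows_filtered, rows_errored = r$rows_errored,
    rows_transformed = r$rows_transformed, nodes = r$nodes, edges = r$edges,
    warnings = length(r$warnings)
  )
}
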