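#' KGX TSV dialect
#'
#' Parameters of the flattened tab-separated serialization: field separator,
#' the delimiter used inside multivalued cells, and the required columns for
#' each table. An empty cell means the property is absent; list-valued cells
#' must not contain a literal separator character.
#'
#' @param field_separator Column separator (tab by default).
#' @param list_delimiter Delimiter within multivalued cells (`"|"`).
#' @return An object of class `kgx_dialect`.
#' @export
kgx_dialect <- function(field_separator = "\t", list_delimiter = "|") {
  structure(
    list(
      field_separator = field_separator,
      list_delimiter = list_delimiter,
      node_required_columns = kgx_node_required,
      edge_required_columns = kgx_edge_required
    ),
    class = "kgx_dialect"
  )
}

# Canonical serialization: nodes sorted by id; edges by (subject, predicate,
# object, knowledge_source); required columns first, the rest alphabetical;
# list cells collapsed with the dialect delimiter. Returns list of two
# character vectors of lines (header first).
kgx_serialize <- function(g, dialect = kgx_dialect()) {
  stopifnot(is_kg_graph(g))
  nodes <- g$nodes[order_c(g$nodes$id), , drop = FALSE]
  ks <- collapse_list_col(g$edges$knowledge_source, dialect$list_delimiter)
  edges <- g$edges[order_c(g$edges$subject, g$edges$predicate,
                           g$edges$object, ks), , drop = FALSE]
  list(
    nodes = table_to_lines(nodes, dialect),
    edges = table_to_lines(edges, dialect)
  )
}

table_to_lines <- function(x, dialect) {
  cells <- purrr::map(x, function(col) {
    out <- collapse_list_col(col, dialect$list_delimiter)
    bad <- grepl(dialect$field_separator, out, fixed = TRUE) | grepl("\n", out, fixed = TRUE)
    if (any(bad)) {
      abort("Cell values may not contain the field separator or newlines",
            class = "kgforge_format_error")
    }
    out
  })
  header <- paste(names(x), collapse = dialect$field_separator)
  if (nrow(x) == 0) return(header)
  body <- do.call(paste, c(cells, sep = dialect$field_separator))
  c(header, body)
}

#' Write a property graph as KGX TSV
#'
#' Output is deterministic — rows and columns are canonically ordered — so
#' rewriting the same graph yields byte-identical files and versioned builds
#' stay diffable. `read_kgx()` on the output reproduces the graph.
#'
#' @param g A [kg_graph].
#' @param out_dir Directory to write into (created if needed).
#' @param dialect A [kgx_dialect].
#' @param nodes_file,edges_file File names within `out_dir`.
#' @return Named character vector with the two paths, invisibly.
#' @export
write_kgx <- function(g, out_dir, dialect = kgx_dialect(),
                      nodes_file = "nodes.tsv", edges_file = "edges.tsv") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort(sprintf("Cannot create output directory: %s", out_dir),
          class = "kgforge_io_error")
  }
  ser <- kgx_serialize(g, dialect)
  paths <- c(nodes = file.path(out_dir, nodes_file),
             edges = file.path(out_dir, edges_file))
  writeLines(ser$nodes, paths[["nodes"]], useBytes = TRUE)
  writeLines(ser$edges, paths[["edges"]], useBytes = TRUE)
  invisible(paths)
}

#' Read a property graph from KGX TSV
#'
#' Each non-empty row of the node file becomes a node keyed by `id`; each row
#' of the edge file an edge. Unknown columns are preserved as properties.
#' Multivalued columns are split on the dialect's list delimiter.
#'
#' @param nodes_file,edges_file Paths to the two TSV files.
#' @param dialect A [kgx_dialect].
#' @return A [kg_graph].
#' @export
read_kgx <- function(nodes_file, edges_file, dialect = kgx_dialect()) {
  nodes <- read_kgx_table(nodes_file, dialect, dialect$node_required_columns,
                          kgx_node_list_cols)
  edges <- read_kgx_table(edges_file, dialect, dialect$edge_required_columns,
                          kgx_edge_list_cols)
  dup <- nodes$id[duplicated(nodes$id)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicate node id(s) in %s: %s", nodes_file,
                  paste(sort_c(unique(dup)), collapse = ", ")),
          class = "kgforge_format_error")
  }
  kg_graph(nodes, edges)
}

read_kgx_table <- function(path, dialect, required, list_cols) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "kgforge_io_error")
  }
  x <- suppressWarnings(readr::read_delim(
    path, delim = dialect$field_separator, quote = "",
    col_types = readr::cols(.default = readr::col_character()),
    na = "", progress = FALSE, show_col_types = FALSE,
    lazy = FALSE
  ))
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    abort(sprintf("Malformed row(s) in %s at line(s): %s", path,
                  paste(unique(probs$row), collapse = ", ")),
          class = "kgforge_format_error")
  }
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s", path,
                  paste(missing, collapse = ", ")),
          class = "kgforge_format_error")
  }
  for (col in intersect(list_cols, names(x))) {
    x[[col]] <- purrr::map(x[[col]], function(v) {
      if (is.na(v)) character(0)
      else strsplit(v, dialect$list_delimiter, fixed = TRUE)[[1]]
    })
  }
  x
}

#' Read a KGX graph directory
#'
#' Convenience wrapper for the `nodes.tsv` / `edges.tsv` pair written by
#' [write_kgx()] and the build layout's `transformed/<SOURCE>/` directories.
#'
#' @param dir Directory containing `nodes.tsv` and `edges.tsv`.
#' @param dialect A [kgx_dialect].
#' @return A [kg_graph].
#' @export
read_kgx_dir <- function(dir, dialect = kgx_dialect()) {
  read_kgx(file.path(dir, "nodes.tsv"), file.path(dir, "edges.tsv"), dialect)
}
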