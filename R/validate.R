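validation_rules <- c("UNKNOWN_CATEGORY", "UNKNOWN_PREDICATE",
                      "PREFIX_CATEGORY_CONFLICT", "UNKNOWN_PREFIX",
                      "MISSING_REQUIRED_FIELD", "DUPLICATE_NODE_ID",
                      "DANGLING_EDGE")

issue_row <- function(rule_id, severity, target, message) {
  tibble::tibble(rule_id = rule_id, severity = severity, target = target,
                 message = message)
}

edge_key <- function(edges) {
  sprintf("%s--%s->%s",
          ifelse(is.na(edges$subject), "", edges$subject),
          ifelse(is.na(edges$predicate), "", edges$predicate),
          ifelse(is.na(edges$object), "", edges$object))
}

#' Validate a graph against the data model
#'
#' Checks compliance with the data model and reports typed, machine-readable
#' issues rather than failing fast, so a build can surface every problem at
#' once. Rules:
#'
#' * `UNKNOWN_CATEGORY` (error): a node category absent from the model.
#' * `UNKNOWN_PREDICATE` (error): an edge predicate absent from the model.
#' * `PREFIX_CATEGORY_CONFLICT` (error): a node whose primary (first)
#'   category is neither the category mapped from its CURIE prefix nor an
#'   ancestor or descendant of it — e.g. an HP (phenotype) identifier typed
#'   as `biolink:Gene`. Typing it as the root category is a warning-free
#'   generalization; a non-lineal category is an error.
#' * `UNKNOWN_PREFIX` (warning): a node prefix in neither the category map
#'   nor the IRI map.
#' * `MISSING_REQUIRED_FIELD` (error): an empty core-triple member.
#' * `DUPLICATE_NODE_ID` (error): a node id occurring more than once.
#' * `DANGLING_EDGE` (error): an edge endpoint with no node.
#'
#' Issues are sorted by (severity, rule_id, target); an empty result means
#' the graph is valid. Validation never modifies the graph and never throws
#' on graph content.
#'
#' @param g A [kg_graph].
#' @param model A [kg_model].
#' @return A tibble of class `kg_issues` with columns `rule_id`, `severity`,
#'   `target`, `message`.
#' @examples
#' g <- kg_graph(nodes = tibble::tibble(id = "HP:0002362",
#'                                      category = "biolink:Gene"))
#' validate_graph(g, kg_mini_model())
#' @export
validate_graph <- function(g, model) {
  stopifnot(is_kg_graph(g), is_kg_model(model))
  issues <- list()
  nodes <- g$nodes
  edges <- g$edges

  dup <- unique(nodes$id[duplicated(nodes$id)])
  for (id in dup) {
    issues <- c(issues, list(issue_row(
      "DUPLICATE_NODE_ID", "error", id,
      sprintf("Node id '%s' occurs %d times", id, sum(nodes$id == id)))))
  }

  known_cats <- names(model$categories)
  for (i in seq_len(nrow(nodes))) {
    id <- nodes$id[i]
    cats <- nodes$category[[i]]
    for (ct in setdiff(cats, known_cats)) {
      issues <- c(issues, list(issue_row(
        "UNKNOWN_CATEGORY", "error", id,
        sprintf("Node '%s' has category '%s' not in the model", id, ct))))
    }
    if (is.na(id) || !curie_is_wellformed(id)) next
    prefix <- curie_prefix(id)
    mapped <- model$prefix_categories[prefix]
    if (is.na(mapped)) {
      if (!prefix %in% names(model$prefixes)) {
        issues <- c(issues, list(issue_row(
          "UNKNOWN_PREFIX", "warning", id,
          sprintf("Prefix '%s' of node '%s' is in neither prefix map",
                  prefix, id))))
      }
    } else if (length(cats) > 0 && cats[1] %in% known_cats) {
      lineal <- unique(c(unname(mapped),
                         term_ancestors(model$categories, unname(mapped)),
                         term_descendants(model$categories, unname(mapped))))
      if (!cats[1] %in% lineal) {
        issues <- c(issues, list(issue_row(
          "PREFIX_CATEGORY_CONFLICT", "error", id,
          sprintf(
            "Node '%s' is typed '%s' but prefix '%s' maps to '%s' (not an ancestor or descendant)",
            id, cats[1], prefix, unname(mapped)))))
      }
    }
  }

  keys <- edge_key(edges)
  known_preds <- names(model$predicates)
  node_ids <- unique(nodes$id)
  for (i in seq_len(nrow(edges))) {
    key <- keys[i]
    for (field in c("subject", "predicate", "object")) {
      if (is_empty_scalar(edges[[field]][i] %||% NA_character_)) {
        issues <- c(issues, list(issue_row(
          "MISSING_REQUIRED_FIELD", "error", key,
          sprintf("Edge '%s' is missing its %s", key, field))))
      }
    }
    pred <- edges$predicate[i]
    if (!is.na(pred) && !pred %in% known_preds) {
      issues <- c(issues, list(issue_row(
        "UNKNOWN_PREDICATE", "error", key,
        sprintf("Edge '%s' uses predicate '%s' not in the model", key, pred))))
    }
    for (field in c("subject", "object")) {
      endpoint <- edges[[field]][i]
      if (!is.na(endpoint) && !endpoint %in% node_ids) {
        issues <- c(issues, list(issue_row(
          "DANGLING_EDGE", "error", key,
          sprintf("Edge '%s' references missing node '%s'", key, endpoint))))
      }
    }
  }

  out <- if (length(issues) == 0) {
    issue_row(character(), character(), character(), character())
  } else {
    dplyr::bind_rows(issues)
  }
  out <- out[order_c(match(out$severity, c("error", "warning")),
                     out$rule_id, out$target), , drop = FALSE]
  structure(out, class = c("kg_issues", class(tibble::tibble())))
}

#' Summarize validation issues
#'
#' Counts by rule and severity, as the summary JSON schema.
#'
#' @param issues A `kg_issues` tibble from [validate_graph()].
#' @return A tibble with columns `rule_id`, `severity`, `n`.
#' @export
issue_summary <- function(issues) {
  dplyr::count(tibble::as_tibble(issues), .data$rule_id, .data$severity,
               name = "n")
}

#' Write a validation report
#'
#' Writes `issues.jsonl` (one issue per line) and `summary.json` (counts by
#' rule and severity plus an overall `valid` flag).
#'
#' @param issues A `kg_issues` tibble.
#' @param out_dir Directory to write into.
#' @return Paths written, invisibly.
#' @export
write_validation_report <- function(issues, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  issues <- tibble::as_tibble(issues)
  jsonl <- file.path(out_dir, "issues.jsonl")
  lines <- purrr::pmap_chr(issues, function(rule_id, severity, target, message) {
    as.character(jsonlite::toJSON(
      list(rule_id = rule_id, severity = severity, target = target,
           message = message), auto_unbox = TRUE))
  })
  writeLines(lines, jsonl, useBytes = TRUE)
  counts <- issue_summary(issues)
  write_json_file(list(
    valid = !any(issues$severity == "error"),
    n_issues = nrow(issues),
    n_errors = sum(issues$severity == "error"),
    n_warnings = sum(issues$severity == "warning"),
    by_rule = purrr::pmap(counts, function(rule_id, severity, n) {
      list(rule_id = rule_id, severity = severity, n = n)
    })
  ), file.path(out_dir, "summary.json"))
  invisible(c(jsonl, file.path(out_dir, "summary.json")))
}
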