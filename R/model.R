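#' Construct a Biolink-style data model
#'
#' The data model drives typing, validation and category-aware filtering. It
#' holds two single-parent hierarchies (entity categories and association
#' predicates), a prefix -> category map used for automatic category
#' assignment, a prefix -> IRI base map used for CURIE expansion, and a
#' default (root) category. Hierarchies are trees: each term has at most one
#' parent and the structure must be acyclic. Users may substitute any model
#' file of the same schema for the bundled miniature model.
#'
#' @param categories Named character vector or list: category CURIE -> parent
#'   category CURIE (or `NA`/`NULL` for roots).
#' @param predicates Same shape, for predicates.
#' @param prefix_categories Named character vector: CURIE prefix -> category.
#' @param prefixes Named character vector: CURIE prefix -> IRI base.
#' @param default_category Category assigned when a prefix is unmapped;
#'   appended to every assignment (typically the model root).
#' @return An object of class `kg_model`.
#' @seealso [read_model()], [kg_mini_model()], [assign_categories()]
#' @export
kg_model <- function(categories, predicates, prefix_categories, prefixes,
                     default_category) {
  categories <- as_parent_map(categories, "categories")
  predicates <- as_parent_map(predicates, "predicates")
  check_hierarchy(categories, "categories")
  check_hierarchy(predicates, "predicates")
  prefix_categories <- unlist(prefix_categories) %||% character()
  prefixes <- unlist(prefixes) %||% character()
  if (!default_category %in% names(categories)) {
    abort(sprintf("default_category '%s' is not a category in the model",
                  default_category), class = "kgforge_model_error")
  }
  unknown <- setdiff(unname(prefix_categories), names(categories))
  if (length(unknown) > 0) {
    abort(sprintf("prefix_categories maps to unknown categories: %s",
                  paste(sort_c(unknown), collapse = ", ")),
          class = "kgforge_model_error")
  }
  structure(
    list(
      categories = categories,
      predicates = predicates,
      prefix_categories = prefix_categories,
      prefixes = prefixes,
      default_category = default_category
    ),
    class = "kg_model"
  )
}

as_parent_map <- function(x, what) {
  if (length(x) == 0) return(stats::setNames(character(), character()))
  vals <- purrr::map_chr(x, function(v) {
    if (is.null(v) || length(v) == 0 || is.na(v)) NA_character_ else as.character(v)
  })
  if (is.null(names(x)) || any(names(x) == "")) {
    abort(sprintf("All %s entries must be named", what),
          class = "kgforge_model_error")
  }
  stats::setNames(vals, names(x))
}

check_hierarchy <- function(parents, what) {
  missing <- setdiff(stats::na.omit(unname(parents)), names(parents))
  if (length(missing) > 0) {
    abort(sprintf("%s hierarchy references undeclared parent(s): %s",
                  what, paste(sort_c(missing), collapse = ", ")),
          class = "kgforge_model_error")
  }
  for (term in names(parents)) {
    seen <- character()
    cur <- term
    while (!is.na(parents[[cur]])) {
      seen <- c(seen, cur)
      cur <- parents[[cur]]
      if (cur %in% seen) {
        abort(sprintf("%s hierarchy contains a cycle through '%s'", what, cur),
              class = "kgforge_model_error")
      }
    }
  }
  invisible(TRUE)
}

#' @rdname kg_model
#' @param x Object to test.
#' @export
is_kg_model <- function(x) inherits(x, "kg_model")

#' @export
print.kg_model <- function(x, ...) {
  cat(sprintf(
    "<kg_model> %d categories, %d predicates, %d typed prefixes, %d IRI prefixes\n",
    length(x$categories), length(x$predicates),
    length(x$prefix_categories), length(x$prefixes)))
  cat(sprintf("default category: %s\n", x$default_category))
  invisible(x)
}

#' Read a data model from YAML
#'
#' The file holds keys `categories` and `predicates` (term -> parent or null),
#' `prefix_categories` (prefix -> category), `prefixes` (prefix -> IRI base)
#' and `default_category`.
#'
#' @param path Path to a model YAML file.
#' @return A [kg_model].
#' @export
read_model <- function(path) {
  y <- read_yaml_file(path)
  for (key in c("categories", "predicates", "prefix_categories", "prefixes",
                "default_category")) {
    if (is.null(y[[key]])) {
      abort(sprintf("Model file %s is missing key '%s'", path, key),
            class = "kgforge_model_error")
    }
  }
  kg_model(y$categories, y$predicates, y$prefix_categories, y$prefixes,
           y$default_category)
}

#' The bundled miniature data model
#'
#' A small Biolink-flavoured model sufficient for drug-protein-disease-
#' phenotype graphs: `biolink:NamedThing` root; `biolink:Gene` and
#' `biolink:Protein` under `biolink:GeneOrGeneProduct`; chemical, disease,
#' phenotype and ontology-class categories; a six-predicate hierarchy rooted
#' at `biolink:related_to`; and prefix maps for HP, MONDO, CHEBI, GO, HGNC,
#' UniProtKB and FOODON.
#'
#' @return A [kg_model].
#' @export
kg_mini_model <- function() {
  read_model(system.file("extdata", "mini-model.yaml", package = "kgforge",
                         mustWork = TRUE))
}

# Strict ancestors, nearest first.
term_ancestors <- function(parents, term) {
  out <- character()
  cur <- term
  while (!is.na(parents[[cur]])) {
    cur <- parents[[cur]]
    out <- c(out, cur)
  }
  out
}

term_depth <- function(parents, term) {
  if (!term %in% names(parents)) return(0L)
  length(term_ancestors(parents, term))
}

term_descendants <- function(parents, term) {
  frontier <- term
  out <- term
  repeat {
    children <- names(parents)[!is.na(parents) & parents %in% frontier]
    children <- setdiff(children, out)
    if (length(children) == 0) break
    out <- c(out, children)
    frontier <- children
  }
  out
}

#' Automatic category assignment from a CURIE's namespace
#'
#' Looks up the CURIE's prefix in the model's prefix -> category map and
#' returns the mapped category followed by its ancestors up to, and always
#' including, the model's default category, most specific first. Unmapped
#' prefixes fall back to the default category alone. Prefix matching is exact
#' on the prefix token.
#'
#' @param id Character vector of CURIEs.
#' @param model A [kg_model].
#' @return For a single id, a character vector of categories; for several, a
#'   list of such vectors.
#' @examples
#' assign_categories("HP:0002027", kg_mini_model())
#' @export
assign_categories <- function(id, model) {
  stopifnot(is_kg_model(model))
  parsed <- curie_parse(id)
  out <- purrr::map(parsed$prefix, function(p) {
    mapped <- model$prefix_categories[p]
    if (is.na(mapped)) return(model$default_category)
    unique(c(unname(mapped), term_ancestors(model$categories, unname(mapped)),
             model$default_category))
  })
  if (length(out) == 1) out[[1]] else out
}

#' Transitive descendants of a category or predicate
#'
#' Returns the term itself plus all transitive children in the model's
#' hierarchy, supporting category-aware filtering that retains all
#' subcategories.
#'
#' @param model A [kg_model].
#' @param category,predicate A term present in the respective hierarchy.
#' @return Character vector of terms (always contains the input).
#' @examples
#' category_descendants(kg_mini_model(), "biolink:GeneOrGeneProduct")
#' @export
category_descendants <- function(model, category) {
  stopifnot(is_kg_model(model))
  if (!category %in% names(model$categories)) {
    abort(sprintf("Unknown category '%s'", category),
          class = "kgforge_model_error")
  }
  term_descendants(model$categories, category)
}

#' @rdname category_descendants
#' @export
predicate_descendants <- function(model, predicate) {
  stopifnot(is_kg_model(model))
  if (!predicate %in% names(model$predicates)) {
    abort(sprintf("Unknown predicate '%s'", predicate),
          class = "kgforge_model_error")
  }
  term_descendants(model$predicates, predicate)
}

# Sort categories most-specific-first (depth descending), stable for ties.
sort_categories_by_depth <- function(cats, model) {
  if (length(cats) <= 1) return(cats)
  depths <- purrr::map_int(cats, function(ct) {
    as.integer(term_depth(model$categories, ct))
  })
  cats[order(-depths)]
}

#' Tidy a data model into a term table
#'
#' @param x A [kg_model].
#' @param ... Unused.
#' @return A tibble with one row per category or predicate: `term`, `kind`,
#'   `parent`, `depth`.
#' @export
tidy.kg_model <- function(x, ...) {
  one <- function(parents, kind) {
    tibble::tibble(
      term = names(parents),
      kind = kind,
      parent = unname(parents),
      depth = purrr::map_int(names(parents),
                             function(t) as.integer(term_depth(parents, t)))
    )
  }
  dplyr::bind_rows(one(x$categories, "category"), one(x$predicates, "predicate"))
}
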