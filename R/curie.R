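#' Parse CURIEs into prefix and local identifier
#'
#' A CURIE (compact URI) has the form `prefix:local_id`, e.g. `HP:0002027`.
#' The split is made at the *first* colon only, so local identifiers may
#' themselves contain colons (as some sources emit). The prefix must be
#' non-empty.
#'
#' @param x Character vector of CURIEs.
#' @return A tibble with columns `curie`, `prefix`, `local_id`.
#' @examples
#' curie_parse(c("HP:0002027", "MONDO:0004335"))
#' @export
curie_parse <- function(x) {
  x <- as.character(x)
  bad <- !curie_is_wellformed(x)
  if (any(bad)) {
    abort(
      sprintf("Malformed CURIE(s): %s",
              paste(sprintf("'%s'", utils::head(x[bad], 5L)), collapse = ", ")),
      class = "kgforge_parse_error"
    )
  }
  tibble::tibble(
    curie = x,
    prefix = sub(":.*$", "", x),
    local_id = sub("^[^:]*:", "", x)
  )
}

#' @rdname curie_parse
#' @export
curie_is_wellformed <- function(x) {
  !is.na(x) & grepl("^[^:]+:", as.character(x))
}

curie_prefix <- function(x) sub(":.*$", "", as.character(x))

#' Expand a CURIE to a full IRI
#'
#' Expansion concatenates the prefix's IRI base (from the data model's prefix
#' map) with the local identifier. `contract_iri()` is its inverse: it matches
#' the longest IRI base in the map and rewrites to `prefix:local_id`, so
#' `contract_iri(expand_curie(x, m), m) == x` whenever the prefix is mapped.
#'
#' @param x Character vector of CURIEs (for `expand_curie`) or IRIs (for
#'   `contract_iri`).
#' @param model A [kg_model] providing the prefix -> IRI base map.
#' @return Character vector of IRIs (`expand_curie`) or CURIEs with unmatched
#'   IRIs returned unchanged (`contract_iri`).
#' @examples
#' m <- kg_mini_model()
#' expand_curie("HP:0002027", m)
#' contract_iri("http://purl.obolibrary.org/obo/HP_0002027", m)
#' @export
expand_curie <- function(x, model) {
  stopifnot(is_kg_model(model))
  parsed <- curie_parse(x)
  unknown <- setdiff(unique(parsed$prefix), names(model$prefixes))
  if (length(unknown) > 0) {
    abort(
      sprintf("Prefix(es) not in the model's IRI map: %s",
              paste(sort_c(unknown), collapse = ", ")),
      class = "kgforge_unmappable_prefix"
    )
  }
  paste0(unname(model$prefixes[parsed$prefix]), parsed$local_id)
}

#' @rdname expand_curie
#' @export
contract_iri <- function(x, model) {
  stopifnot(is_kg_model(model))
  bases <- model$prefixes
  # longest base first so e.g. ".../obo/HP_" beats a hypothetical ".../obo/"
  ord <- order(-nchar(bases), names(bases), method = "radix")
  bases <- bases[ord]
  out <- as.character(x)
  for (i in seq_along(out)) {
    for (j in seq_along(bases)) {
      if (startsWith(out[i], bases[[j]])) {
        out[i] <- paste0(names(bases)[j], ":",
                         substring(out[i], nchar(bases[[j]]) + 1L))
        break
      }
    }
  }
  out
}
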