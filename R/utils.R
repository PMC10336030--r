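#' @importFrom rlang %||% abort warn inform
#' @importFrom dplyr %>%
NULL

# Locale-independent character sort (C collation) so serialized artifacts are
# byte-identical across machines.
sort_c <- function(x) x[order(x, method = "radix")]

order_c <- function(...) order(..., method = "radix")

# Order-preserving union of character vectors, dropping NA and "".
union_keep_order <- function(...) {
  x <- unlist(list(...), use.names = FALSE)
  x <- x[!is.na(x) & x != ""]
  unique(x)
}

# First non-empty scalar in input order; NA if none.
first_non_empty <- function(...) {
  for (v in c(...)) {
    if (!is.na(v) && !identical(v, "")) return(v)
  }
  NA_character_
}

is_empty_scalar <- function(x) is.na(x) | x == ""

sha256_file <- function(path) digest::digest(file = path, algo = "sha256")

# Wrap an atomic character column into a list-of-character column
# (NA -> character(0)); list columns pass through unchanged.
as_list_col <- function(x) {
  if (is.list(x)) {
    purrr::map(x, function(v) {
      v <- as.character(v)
      v[!is.na(v) & v != ""]
    })
  } else {
    purrr::map(as.character(x), function(v) {
      if (length(v) == 0 || is.na(v) || v == "") character(0) else v
    })
  }
}

# Collapse a list column to delimiter-joined strings ("" when empty).
collapse_list_col <- function(x, delim = "|") {
  if (!is.list(x)) {
    out <- as.character(x)
    out[is.na(out)] <- ""
    return(out)
  }
  purrr::map_chr(x, function(v) paste(v, collapse = delim))
}

read_yaml_file <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "kgforge_io_error")
  }
  yaml::read_yaml(path)
}

write_json_file <- function(x, path, pretty = TRUE) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = pretty,
                       null = "null")
  invisible(path)
}
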