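#' Read a download configuration
#'
#' `download.yaml` is a list of download specs: `url` (http(s), file scheme,
#' or a plain path), `local_name` (unique within the project), optional
#' `sha256` hex digest and optional `decompress` flag for gzipped sources.
#'
#' @param path Path to a download YAML file.
#' @return A list of class `kg_download_config`.
#' @export
read_download_config <- function(path) {
  y <- read_yaml_file(path)
  specs <- if (!is.null(y$downloads)) y$downloads else y
  for (s in specs) {
    if (is.null(s$url) || is.null(s$local_name)) {
      abort(sprintf("%s: every download spec needs url and local_name", path),
            class = "kgforge_config_error")
    }
  }
  names_ <- purrr::map_chr(specs, "local_name")
  if (anyDuplicated(names_)) {
    abort(sprintf("%s: duplicate local_name(s): %s", path,
                  paste(unique(names_[duplicated(names_)]), collapse = ", ")),
          class = "kgforge_config_error")
  }
  structure(list(specs = specs, config_dir = dirname(path)),
            class = "kg_download_config")
}

resolve_url <- function(url, base_dir) {
  if (grepl("^file:", url)) {
    path <- sub("^file://", "", sub("^file:", "", url))
    if (!startsWith(path, "/")) path <- file.path(base_dir, path)
    return(list(scheme = "file", path = path))
  }
  if (grepl("^https?://", url)) return(list(scheme = "http", path = url))
  # plain path
  path <- if (startsWith(url, "/")) url else file.path(base_dir, url)
  list(scheme = "file", path = path)
}

#' Retrieve upstream sources with caching
#'
#' For each spec the cache is consulted first: a cached copy whose digest
#' matches (or with no digest declared) is reused without re-fetching.
#' Otherwise the source is fetched into the cache. If a fetch fails but a
#' cached copy exists, the cached copy is used with a warning so a build can
#' proceed through transient upstream outages; a fetch failure with no cache
#' is a hard error, as is a digest mismatch after a fresh fetch. With
#' `offline = TRUE` nothing is fetched and the cache is required.
#'
#' @param specs A `kg_download_config`, its `specs` list, or a path to
#'   `download.yaml`.
#' @param cache_dir Writable cache directory.
#' @param offline Forbid network/file retrieval; require cached copies.
#' @param base_dir Directory against which relative `file:` URLs resolve
#'   (defaults to the config's directory).
#' @return A tibble: `local_name`, `url`, `path`, `cache_hit`, `sha256`.
#' @export
fetch_sources <- function(specs, cache_dir, offline = FALSE, base_dir = NULL) {
  if (is.character(specs) && length(specs) == 1) {
    specs <- read_download_config(specs)
  }
  if (inherits(specs, "kg_download_config")) {
    base_dir <- base_dir %||% specs$config_dir
    specs <- specs$specs
  }
  base_dir <- base_dir %||% "."
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)

  rows <- list()
  for (s in specs) rows[[length(rows) + 1L]] <- fetch_one(s, cache_dir, offline, base_dir)
  dplyr::bind_rows(rows)
}

fetch_one <- function(s, cache_dir, offline, base_dir) {
  {
    dest <- file.path(cache_dir, s$local_name)
    cached_ok <- file.exists(dest) &&
      (is.null(s$sha256) || identical(sha256_file(dest), s$sha256))
    if (cached_ok) {
      return(tibble::tibble(local_name = s$local_name, url = s$url,
                            path = dest, cache_hit = TRUE,
                            sha256 = sha256_file(dest)))
    }
    if (offline) {
      if (file.exists(dest)) {
        warn(sprintf("Offline: cached copy of '%s' fails its digest; using it anyway",
                     s$local_name))
        return(tibble::tibble(local_name = s$local_name, url = s$url,
                              path = dest, cache_hit = TRUE,
                              sha256 = sha256_file(dest)))
      }
      abort(sprintf("Offline and no cached copy of '%s'", s$local_name),
            class = "kgforge_io_error")
    }
    fetched <- tryCatch({
      loc <- resolve_url(s$url, base_dir)
      tmp <- paste0(dest, ".part")
      if (loc$scheme == "file") {
        if (!file.exists(loc$path)) {
          abort(sprintf("Source file not found: %s", loc$path))
        }
        file.copy(loc$path, tmp, overwrite = TRUE)
      } else {
        utils::download.file(loc$path, tmp, quiet = TRUE, mode = "wb")
      }
      if (isTRUE(s$decompress)) {
        con <- gzfile(tmp, "rb")
        raw_data <- readBin(con, "raw", n = file.size(tmp) * 50 + 1e6)
        close(con)
        writeBin(raw_data, tmp)
      }
      if (!is.null(s$sha256) && !identical(sha256_file(tmp), s$sha256)) {
        unlink(tmp)
        abort(sprintf("Digest mismatch after fetching '%s'", s$local_name),
              class = "kgforge_digest_error")
      }
      file.rename(tmp, dest)
      TRUE
    }, kgforge_digest_error = function(e) rlang::cnd_signal(e),
       error = function(e) e)
    if (inherits(fetched, "error")) {
      if (file.exists(dest)) {
        warn(sprintf("Fetch of '%s' failed (%s); using cached copy",
                     s$local_name, conditionMessage(fetched)))
        return(tibble::tibble(local_name = s$local_name, url = s$url,
                              path = dest, cache_hit = TRUE,
                              sha256 = sha256_file(dest)))
      }
      abort(sprintf("Cannot retrieve '%s' from %s and no cached copy exists: %s",
                    s$local_name, s$url, conditionMessage(fetched)),
            class = "kgforge_io_error")
    }
    tibble::tibble(local_name = s$local_name, url = s$url, path = dest,
                   cache_hit = FALSE, sha256 = sha256_file(dest))
  }
}

#' Read a project configuration
#'
#' `project.yaml` wires one build together: `model` (model YAML), `download`
#' (download YAML), `transforms` (list of transform YAMLs), `merge` (merge
#' YAML) and `validation_fatal` (default `TRUE`: abort the build before
#' merging when any transformed subgraph has an error-severity issue).
#' Relative paths resolve against the project file's directory.
#'
#' @param path Path to a project YAML file.
#' @return A list of class `kg_project_config`.
#' @export
read_project_config <- function(path) {
  y <- read_yaml_file(path)
  for (key in c("model", "download", "transforms", "merge")) {
    if (is.null(y[[key]])) {
      abort(sprintf("%s: project config is missing '%s'", path, key),
            class = "kgforge_config_error")
    }
  }
  y$validation_fatal <- y$validation_fatal %||% TRUE
  dir <- dirname(normalizePath(path))
  rel <- function(p) if (startsWith(p, "/")) p else file.path(dir, p)
  y$model <- rel(y$model)
  y$download <- rel(y$download)
  y$transforms <- purrr::map_chr(y$transforms, rel)
  y$merge <- rel(y$merge)
  y$config_files <- c(path, y$model, y$download, y$transforms, y$merge)
  y$config_dir <- dir
  structure(y, class = "kg_project_config")
}

next_build_version <- function(workspace, date = Sys.Date()) {
  stamp <- format(date, "%Y%m%d")
  if (!dir.exists(file.path(workspace, stamp))) return(stamp)
  n <- 1
  while (dir.exists(file.path(workspace, sprintf("%s.%d", stamp, n)))) n <- n + 1
  sprintf("%s.%d", stamp, n)
}

#' Run an end-to-end versioned build
#'
#' Orchestrates one build: fetch sources into a shared cache and copy them
#' into `raw/`, transform each source into `transformed/<SOURCE>/` (a
#' self-contained KGX subgraph plus its transform report), validate the
#' subgraphs (aborting before the merge when `validation_fatal` and any
#' error-severity issue exists), merge into `merged/`, validate the merged
#' graph into `validation/`, compute statistics into `stats/`, and write a
#' provenance manifest. The build directory is stamped with the build date
#' (`YYYYMMDD`, with a `.n` suffix for same-day rebuilds) and a `current`
#' pointer file is updated on success only; a failed build keeps its partial
#' outputs for debugging and leaves `current` untouched.
#'
#' Identical inputs and configs give byte-identical transformed, merged and
#' stats artifacts (only manifest timestamps differ).
#'
#' @param project_config Path to `project.yaml` (or a
#'   [read_project_config()] result).
#' @param workspace Directory for versioned builds.
#' @param offline Passed to [fetch_sources()].
#' @return The build manifest (class `kg_manifest`), invisibly.
#' @export
run_build <- function(project_config, workspace, offline = FALSE) {
  if (is.character(project_config)) {
    project_config <- read_project_config(project_config)
  }
  stopifnot(inherits(project_config, "kg_project_config"))
  cfg <- project_config
  dir.create(workspace, recursive = TRUE, showWarnings = FALSE)
  version <- next_build_version(workspace)
  build_dir <- file.path(workspace, version)
  dir.create(build_dir, recursive = TRUE)

  manifest <- list(
    build_version = version,
    tool = "kgforge",
    tool_version = as.character(utils::packageVersion("kgforge")),
    started_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    status = "running",
    sources = list(),
    configs = purrr::map(cfg$config_files, function(p) {
      list(path = basename(p), sha256 = sha256_file(p))
    }),
    outputs = list()
  )
  write_manifest <- function() {
    write_json_file(manifest, file.path(build_dir, "manifest.json"))
  }

  fail <- function(stage, e) {
    manifest$status <<- sprintf("failed at %s", stage)
    manifest$error <<- conditionMessage(e)
    write_manifest()
    abort(sprintf("Build %s failed at %s stage: %s", version, stage,
                  conditionMessage(e)),
          class = "kgforge_build_error", parent = e)
  }

  model <- tryCatch(read_model(cfg$model), error = function(e) fail("config", e))

  # download
  fetched <- tryCatch({
    dl <- read_download_config(cfg$download)
    fetch_sources(dl, cache_dir = file.path(workspace, "cache"),
                  offline = offline)
  }, error = function(e) fail("download", e))
  raw_dir <- file.path(build_dir, "raw")
  dir.create(raw_dir, recursive = TRUE)
  file.copy(fetched$path, file.path(raw_dir, fetched$local_name),
            overwrite = TRUE)
  manifest$sources <- purrr::pmap(fetched,
    function(local_name, url, path, cache_hit, sha256) {
      list(name = local_name, url = url,
           retrieved_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
           sha256 = sha256, cache_hit = cache_hit)
    })

  # transform
  transformed_dir <- file.path(build_dir, "transformed")
  results <- tryCatch({
    purrr::map(cfg$transforms, function(tpath) {
      tcfg <- read_transform_config(tpath)
      res <- suppressWarnings(
        transform_source(tcfg, model, input_dir = raw_dir))
      out <- file.path(transformed_dir, tcfg$source_name)
      write_kgx(res$graph, out)
      write_json_file(res$report, file.path(out, "transform_report.json"))
      res
    })
  }, error = function(e) fail("transform", e))

  # validate transformed subgraphs (the fatality gate)
  val_dir <- file.path(build_dir, "validation")
  pre_issues <- tryCatch({
    purrr::map(results, function(res) validate_graph(res$graph, model))
  }, error = function(e) fail("validation", e))
  n_errors <- sum(purrr::map_int(pre_issues, function(x) {
    sum(x$severity == "error")
  }))
  if (n_errors > 0 && isTRUE(cfg$validation_fatal)) {
    all_issues <- dplyr::bind_rows(purrr::map(pre_issues, tibble::as_tibble))
    write_validation_report(all_issues, val_dir)
    fail("validation", simpleError(sprintf(
      "%d validation error(s) in transformed subgraphs (see validation/)",
      n_errors)))
  }

  # merge
  merged <- tryCatch({
    run_merge(cfg$merge, model, transformed_dir = transformed_dir,
              raw_dir = raw_dir, out_dir = file.path(build_dir, "merged"))
  }, error = function(e) fail("merge", e))

  # validate merged graph + stats
  tryCatch({
    issues <- validate_graph(merged$graph, model)
    write_validation_report(issues, val_dir)
    stats <- compute_stats(merged$graph)
    write_stats(stats, file.path(build_dir, "stats"))
  }, error = function(e) fail("reporting", e))

  outputs <- list.files(build_dir, recursive = TRUE, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest$outputs <- purrr::map(sort_c(outputs), function(p) {
    list(path = sub(paste0("^", build_dir, "/"), "", p), sha256 = sha256_file(p))
  })
  manifest$status <- "success"
  manifest$finished_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  write_manifest()
  writeLines(version, file.path(workspace, "current"), useBytes = TRUE)
  invisible(structure(manifest, class = "kg_manifest"))
}

#' @export
print.kg_manifest <- function(x, ...) {
  cat(sprintf("<kg_manifest> build %s (%s) — %s\n", x$build_version,
              x$tool_version, x$status))
  cat(sprintf("  %d source(s), %d output file(s)\n", length(x$sources),
              length(x$outputs)))
  invisible(x)
}
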