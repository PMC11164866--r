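# Reference-database management and end-to-end authentication.

#' Build a reference database from enrolment images
#'
#' Runs the extraction chain and SIFT feature extraction over every
#' reference image and persists the results as a database directory:
#' \code{manifest.json}, \code{references/} (copies of the enrolment
#' images) and \code{features/} (one schema-versioned cache per entry).
#' Re-building over an existing directory reuses caches whose SIFT
#' parameters match, so adding one image costs one feature extraction.
#'
#' The build is atomic with respect to failures: unreadable or
#' unprocessable images are collected and reported in a single error, and
#' no manifest is written.
#'
#' @param image_paths character vector of reference image paths.
#' @param dir database directory to create or update.
#' @param config the [match_config()] recorded in the manifest as the
#'   database's operating point.
#' @param sift [sift_params()] used for feature extraction.
#' @param ids entry ids; default the file names without extension. Must be
#'   unique.
#' @param max_features feature cap per entry (\code{Inf} = uncapped).
#' @return an object of class \code{epuf_db}: list with \code{dir},
#'   \code{entries} (data frame of id and reference path), \code{features}
#'   (named list of \code{feature_set}s), the manifest, and
#'   \code{n_extracted}, the number of images actually (re-)processed.
#' @export
build_database <- function(image_paths, dir, config = match_config(),
                           sift = sift_params(),
                           ids = tools::file_path_sans_ext(
                             basename(image_paths)),
                           max_features = Inf) {
  if (length(image_paths) < 1L) {
    stop("at least one reference image is required", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate database ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  dir.create(file.path(dir, "references"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "features"), recursive = TRUE,
             showWarnings = FALSE)
  feats <- vector("list", length(ids))
  names(feats) <- ids
  errors <- character(0)
  n_extracted <- 0L
  for (i in seq_along(ids)) {
    cache_path <- file.path(dir, "features", paste0(ids[i], ".rds"))
    cached <- NULL
    if (file.exists(cache_path)) {
      cached <- tryCatch(load_features(cache_path), error = function(e) NULL)
      if (!is.null(cached) &&
          !identical(unclass(cached$params), unclass(sift))) {
        cached <- NULL  # parameters changed; re-extract
      }
    }
    if (is.null(cached)) {
      cached <- tryCatch({
        pat <- process_image(image_paths[i], source_id = ids[i])
        extract_features(pat, max_features = max_features, params = sift)
      }, error = function(e) {
        errors <<- c(errors,
                     sprintf("%s: %s", image_paths[i], conditionMessage(e)))
        NULL
      })
      if (!is.null(cached)) n_extracted <- n_extracted + 1L
    }
    feats[[i]] <- cached
  }
  if (length(errors) > 0L) {
    stop("database build failed for ", length(errors), " image(s):\n  ",
         paste(errors, collapse = "\n  "), call. = FALSE)
  }
  ref_paths <- character(length(ids))
  for (i in seq_along(ids)) {
    ref_paths[i] <- file.path("references",
                              paste0(ids[i], ".", tools::file_ext(
                                image_paths[i])))
    dest <- file.path(dir, ref_paths[i])
    if (!file.exists(dest) ||
        normalizePath(dest, mustWork = FALSE) !=
        normalizePath(image_paths[i], mustWork = FALSE)) {
      file.copy(image_paths[i], dest, overwrite = TRUE)
    }
    save_features(feats[[i]], file.path(dir, "features",
                                        paste0(ids[i], ".rds")))
  }
  manifest <- list(schema_version = FEATURE_CACHE_SCHEMA,
                   match_config = unclass(config),
                   sift_params = unclass(sift),
                   entries = data.frame(id = ids, reference = ref_paths,
                                        stringsAsFactors = FALSE))
  write_json_file(manifest, file.path(dir, "manifest.json"))
  structure(
    list(dir = dir, entries = manifest$entries, features = feats,
         manifest = manifest, n_extracted = n_extracted),
    class = "epuf_db"
  )
}

#' Load a reference database from disk
#'
#' @param dir a database directory written by [build_database()].
#' @return an \code{epuf_db}.
#' @export
load_database <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) {
    stop("no database manifest at ", dir, call. = FALSE)
  }
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (!identical(as.integer(manifest$schema_version),
                 FEATURE_CACHE_SCHEMA)) {
    stop("database schema version mismatch", call. = FALSE)
  }
  ids <- manifest$entries$id
  feats <- lapply(ids, function(id) {
    load_features(file.path(dir, "features", paste0(id, ".rds")))
  })
  names(feats) <- ids
  structure(
    list(dir = dir, entries = manifest$entries, features = feats,
         manifest = manifest, n_extracted = 0L),
    class = "epuf_db"
  )
}

#' @export
print.epuf_db <- function(x, ...) {
  cat(sprintf("ePUF database (%d entries) at %s\n", nrow(x$entries),
              x$dir %||% "<memory>"))
  invisible(x)
}

#' Authenticate a query image against a reference database
#'
#' Full composition of the pipeline: pattern extraction
#' ([process_image()]), SIFT feature extraction, per-entry match counting
#' at the configured distance ratio and symmetry setting, and the
#' prominence-threshold decision. Extraction failures (unreadable file,
#' no pill, blank tablet) yield a verdict with outcome
#' \code{"unprocessable"} -- deliberately distinct from
#' \code{"unconfident"}, so I/O problems are never reported as
#' authentication failures.
#'
#' @param raw_query query image (path, \code{EBImage::Image} or array), or
#'   a ready-made \code{feature_set}.
#' @param db an \code{epuf_db} (or named list of \code{feature_set}s).
#' @param config a [match_config()].
#' @param true_id optional ground-truth entry id; when given, the verdict's
#'   truth status is filled in via [evaluate_truth()].
#' @return a \code{match_verdict}.
#' @export
authenticate <- function(raw_query, db, config = match_config(),
                         true_id = NULL) {
  fs <- if (inherits(raw_query, "feature_set")) {
    raw_query
  } else {
    sift <- if (inherits(db, "epuf_db")) {
      structure(db$manifest$sift_params, class = "sift_params")
    } else {
      sift_params()
    }
    res <- tryCatch(
      extract_features(process_image(raw_query), params = sift),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      return(structure(
        list(outcome = "unprocessable", best_id = NA_character_,
             N1 = 0L, N2 = 0L, prominence = 0, query_feature_total = 0L,
             truth_status = "not_evaluated", config = config,
             error = conditionMessage(res)),
        class = "match_verdict"))
    }
    res
  }
  counts <- count_matches(fs, db, k = config$k, symmetry = config$symmetry)
  verdict <- decide(counts, config)
  if (!is.null(true_id)) verdict <- evaluate_truth(verdict, true_id)
  verdict
}
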