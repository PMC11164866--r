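# SIFT feature extraction and the on-disk feature cache.

FEATURE_CACHE_SCHEMA <- 1L

#' SIFT parameters
#'
#' The standard SIFT parameterisation: number of scale-space layers per
#' octave, the difference-of-Gaussian contrast threshold (on the [0, 1]
#' intensity scale), the principal-curvature edge-response threshold, the
#' base smoothing sigma, and whether the image is initially upsampled 2x
#' (which roughly doubles the number of detectable small-scale features).
#' These are recorded in every feature cache and database manifest so
#' stored features are self-describing.
#'
#' @param n_octave_layers scale-space layers per octave.
#' @param contrast_threshold minimum refined DoG response.
#' @param edge_threshold maximum principal-curvature ratio.
#' @param sigma base Gaussian sigma of the pyramid.
#' @param upscale logical; start from a 2x upsampled image.
#' @return a named list of class \code{sift_params}.
#' @export
sift_params <- function(n_octave_layers = 3L, contrast_threshold = 0.04,
                        edge_threshold = 10, sigma = 1.6, upscale = TRUE) {
  structure(
    list(n_octave_layers = as.integer(n_octave_layers),
         contrast_threshold = contrast_threshold,
         edge_threshold = edge_threshold, sigma = sigma,
         upscale = isTRUE(upscale)),
    class = "sift_params"
  )
}

#' Extract SIFT features from a pattern image
#'
#' Detects SIFT keypoints and computes their 128-component integer
#' descriptors. Extraction is deterministic: the same image and parameters
#' always yield the same feature set.
#'
#' @param img a [extract_pattern()] result (\code{pattern_image}), or a
#'   grayscale matrix in [0, 1].
#' @param max_features cap on the number of features, keeping the
#'   strongest responses; \code{Inf} (default) keeps all.
#' @param params a [sift_params()] list.
#' @param source_id identifier; defaults to the pattern image's.
#' @return an object of class \code{feature_set}: list with
#'   \code{source_id}, \code{keypoints} (data frame: \code{x}, \code{y},
#'   \code{scale}, \code{angle}, \code{response}, \code{octave}),
#'   \code{descriptors} (integer matrix, one 128-long row per feature),
#'   \code{image_shape} and \code{params}.
#' @export
extract_features <- function(img, max_features = Inf,
                             params = sift_params(), source_id = NULL) {
  if (inherits(img, "pattern_image")) {
    if (is.null(source_id)) source_id <- img$source_id
    m <- img$pixels
  } else if (is.matrix(img)) {
    m <- img
  } else {
    stop("img must be a pattern_image or a grayscale matrix", call. = FALSE)
  }
  if (is.null(source_id)) source_id <- NA_character_
  mf <- if (is.finite(max_features)) as.integer(max_features) else 0L
  res <- .sift_cpp(m, params$n_octave_layers, params$contrast_threshold,
                   params$edge_threshold, params$sigma, params$upscale, mf)
  kp <- as.data.frame(res$keypoints)
  # keypoint matrix rows/cols are the matrix's first/second index = x/y here
  names(kp) <- c("x", "y", "scale", "angle", "response", "octave")
  structure(
    list(source_id = source_id, keypoints = kp,
         descriptors = res$descriptors,
         image_shape = dim(m), params = params),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("SIFT feature set '%s': %d features from a %d x %d image\n",
              x$source_id, nrow(x$descriptors), x$image_shape[1L],
              x$image_shape[2L]))
  invisible(x)
}

#' Number of features in a feature set
#' @param fs a \code{feature_set}.
#' @return integer count.
#' @export
n_features <- function(fs) {
  stopifnot(inherits(fs, "feature_set"))
  nrow(fs$descriptors)
}

#' Persist and reload feature sets
#'
#' Feature caches are written with R's native compressed serialisation
#' (RDS) wrapping a schema-versioned record: schema version, SIFT
#' parameters, source id, image shape, keypoint table and the exact integer
#' descriptor matrix. The round trip is lossless. Files that are not
#' feature caches, or caches written under a different schema version, are
#' rejected with an explicit error rather than reinterpreted.
#'
#' @param fs a \code{feature_set}.
#' @param path file path (conventionally \code{.rds}).
#' @return \code{save_features} returns \code{path} invisibly;
#'   \code{load_features} returns the restored \code{feature_set}.
#' @export
save_features <- function(fs, path) {
  stopifnot(inherits(fs, "feature_set"))
  rec <- list(magic = "epuf-features", schema_version = FEATURE_CACHE_SCHEMA,
              params = unclass(fs$params), source_id = fs$source_id,
              image_shape = fs$image_shape, keypoints = fs$keypoints,
              descriptors = fs$descriptors)
  saveRDS(rec, path)
  invisible(path)
}

#' @rdname save_features
#' @export
load_features <- function(path) {
  rec <- tryCatch(readRDS(path), error = function(e) {
    stop("not a feature cache (unreadable): ", path, call. = FALSE)
  })
  if (!is.list(rec) || !identical(rec$magic, "epuf-features")) {
    stop("not a feature cache (bad magic): ", path, call. = FALSE)
  }
  if (!identical(rec$schema_version, FEATURE_CACHE_SCHEMA)) {
    stop("feature cache schema version mismatch in ", path,
         " (found ", rec$schema_version, ", expected ",
         FEATURE_CACHE_SCHEMA, ")", call. = FALSE)
  }
  structure(
    list(source_id = rec$source_id, keypoints = rec$keypoints,
         descriptors = rec$descriptors, image_shape = rec$image_shape,
         params = structure(rec$params, class = "sift_params")),
    class = "feature_set"
  )
}
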