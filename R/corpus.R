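#' Generate a synthetic ePUF corpus (references, queries, ground truth)
#'
#' Emulates an enrolment-plus-field-capture study: \code{n} tablets receive
#' independent stochastic spot patterns (spray parameters drawn uniformly
#' from \code{spray_ranges}), each is rendered once as a lossless reference
#' image, and each is photographed \code{queries_per_pattern} times under
#' random cellphone-like perturbations drawn from \code{capture_ranges}
#' (JPEG-compressed, as a cellphone would). A key table maps every image to
#' its ground-truth pattern id.
#'
#' All randomness descends from \code{seed}: per-pattern and per-query
#' sub-seeds are drawn once from the master stream, so the same seed
#' reproduces the corpus byte-for-byte.
#'
#' @param n number of distinct patterns (>= 1).
#' @param dir output directory (created if missing); references are written
#'   to \code{references/} as PNG, queries to \code{queries/} as JPEG.
#' @param spray_ranges named list of \code{c(min, max)} ranges for
#'   \code{flow_rate}, \code{translation_speed} and \code{mass_loading}.
#' @param capture_ranges named list of \code{c(min, max)} ranges for
#'   \code{rotation}, \code{tilt}, \code{brightness} and \code{blur}.
#' @param queries_per_pattern perturbed captures per pattern.
#' @param px_per_mm render resolution of the references.
#' @param output_resolution side length of the query captures, px.
#' @param jpeg_quality JPEG quality for query images.
#' @param noise_sigma additive capture noise (8-bit intensity units).
#' @param seed master seed.
#' @return (invisibly) an object of class \code{epuf_corpus}: list with the
#'   corpus \code{dir}, the \code{key} data frame (\code{image_path},
#'   \code{pattern_id}, \code{role}), and the per-image configurations.
#' @export
#' @examples
#' \donttest{
#' corp <- generate_corpus(2, tempfile("corpus"), seed = 7)
#' corp$key
#' }
generate_corpus <- function(n, dir,
                            spray_ranges = list(
                              flow_rate = c(5, 22),
                              translation_speed = c(8, 20),
                              mass_loading = c(1, 2)),
                            capture_ranges = list(
                              rotation = c(0, 360),
                              tilt = c(0, 15),
                              brightness = c(130, 200),
                              blur = c(0.3, 1)),
                            queries_per_pattern = 1L,
                            px_per_mm = 30, output_resolution = 480,
                            jpeg_quality = 85, noise_sigma = 2.5,
                            seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  queries_per_pattern <- as.integer(queries_per_pattern)
  ids <- sprintf("p%03d", seq_len(n))
  if (anyDuplicated(ids)) stop("duplicate pattern ids", call. = FALSE)
  dir.create(file.path(dir, "references"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "queries"), recursive = TRUE,
             showWarnings = FALSE)

  draws <- withr::with_seed(as.integer(seed), {
    nq <- n * queries_per_pattern
    list(
      sub_seeds = sample.int(.Machine$integer.max - 1L, n + nq),
      flow = runif(n, spray_ranges$flow_rate[1], spray_ranges$flow_rate[2]),
      speed = runif(n, spray_ranges$translation_speed[1],
                    spray_ranges$translation_speed[2]),
      mass = runif(n, spray_ranges$mass_loading[1],
                   spray_ranges$mass_loading[2]),
      rotation = runif(nq, capture_ranges$rotation[1],
                       capture_ranges$rotation[2]),
      tilt = runif(nq, capture_ranges$tilt[1], capture_ranges$tilt[2]),
      brightness = runif(nq, capture_ranges$brightness[1],
                         capture_ranges$brightness[2]),
      blur = runif(nq, capture_ranges$blur[1], capture_ranges$blur[2])
    )
  })

  key <- list()
  spray_cfgs <- list()
  capture_cfgs <- list()
  qi <- 0L
  for (i in seq_len(n)) {
    scfg <- spray_config(flow_rate = draws$flow[i],
                         translation_speed = draws$speed[i],
                         mass_loading = draws$mass[i],
                         seed = draws$sub_seeds[i])
    spray_cfgs[[ids[i]]] <- scfg
    ref <- render_tablet(sample_spots(scfg), scfg, px_per_mm = px_per_mm)
    ref_path <- file.path("references", paste0(ids[i], ".png"))
    EBImage::writeImage(ref, file.path(dir, ref_path))
    key[[length(key) + 1L]] <- data.frame(
      image_path = ref_path, pattern_id = ids[i], role = "reference")
    for (q in seq_len(queries_per_pattern)) {
      qi <- qi + 1L
      ccfg <- capture_config(
        rotation = draws$rotation[qi], tilt = draws$tilt[qi],
        brightness_target = draws$brightness[qi],
        blur_sigma = draws$blur[qi],
        output_resolution = output_resolution,
        noise_sigma = noise_sigma,
        seed = draws$sub_seeds[n + qi])
      qid <- paste0(ids[i], "_q", q)
      capture_cfgs[[qid]] <- ccfg
      qimg <- perturb_capture(ref, ccfg)
      q_path <- file.path("queries", paste0(qid, ".jpg"))
      EBImage::writeImage(qimg, file.path(dir, q_path),
                          quality = jpeg_quality)
      key[[length(key) + 1L]] <- data.frame(
        image_path = q_path, pattern_id = ids[i], role = "query")
    }
  }
  key <- do.call(rbind, key)
  write.csv(key, file.path(dir, "key.csv"), row.names = FALSE)
  write_json_file(
    list(n = n, queries_per_pattern = queries_per_pattern,
         px_per_mm = px_per_mm, output_resolution = output_resolution,
         jpeg_quality = jpeg_quality, noise_sigma = noise_sigma,
         seed = as.integer(seed), spray_ranges = spray_ranges,
         capture_ranges = capture_ranges),
    file.path(dir, "corpus.json"))
  invisible(structure(
    list(dir = dir, key = key, spray_configs = spray_cfgs,
         capture_configs = capture_cfgs),
    class = "epuf_corpus"))
}

#' @export
print.epuf_corpus <- function(x, ...) {
  cat(sprintf("ePUF corpus at %s: %d references, %d queries\n", x$dir,
              sum(x$key$role == "reference"), sum(x$key$role == "query")))
  invisible(x)
}
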