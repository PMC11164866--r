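#' Electrospray deposition configuration
#'
#' Bundles the process parameters that govern a simulated electrospray
#' deposition run. The tablet is translated under the spray plume in a
#' zig-zag raster behind a square stencil, so the deposited spot pattern is
#' confined to the stencil window. Spot density rises with solution flow
#' rate and falls with translation speed; dye mass loading controls stain
#' intensity only.
#'
#' @param flow_rate solution flow rate through the emitter, uL/min
#'   (typical working range 5-22).
#' @param translation_speed stage translation speed, mm/s (typical 8-20).
#' @param mass_loading dye mass fraction of the ink, wt\% (typical 1-2).
#' @param passes number of zig-zag passes across the stencil window.
#' @param pitch spacing between passes, mm; \code{passes * pitch} must not
#'   exceed \code{stencil_side}.
#' @param stencil_side side length of the square stencil opening, mm.
#' @param tablet_diameter tablet diameter, mm.
#' @param plume_sigma lateral Gaussian spread of the spray plume about the
#'   translation path, mm.
#' @param deposition_efficiency proportionality constant linking
#'   \code{flow_rate / translation_speed} to the per-mm deposition rate
#'   (spots per mm per unit flow/speed ratio).
#' @param radius_coef,radius_exponent,radius_sdlog the median deposited spot
#'   radius is \code{radius_coef * flow_rate^radius_exponent} mm and
#'   individual radii are lognormal with log-sd \code{radius_sdlog}. This is
#'   a phenomenological stand-in for the electrospray droplet-size scaling
#'   laws (droplet size grows with flow rate); the exponent is exposed so it
#'   can be changed without code edits.
#' @param seed integer RNG seed; a fixed seed makes every downstream draw
#'   reproducible.
#'
#' @return an object of class \code{spray_config}.
#' @seealso [sample_spots()], [render_tablet()]
#' @export
#' @examples
#' cfg <- spray_config(flow_rate = 10, translation_speed = 12, seed = 1)
#' spots <- sample_spots(cfg)
#' nrow(spots$spots)
spray_config <- function(flow_rate = 10, translation_speed = 12,
                         mass_loading = 1.5, passes = 8, pitch = 1,
                         stencil_side = 8, tablet_diameter = 16,
                         plume_sigma = 0.35, deposition_efficiency = 4,
                         radius_coef = 0.032, radius_exponent = 0.5,
                         radius_sdlog = 0.35, seed = 1L) {
  if (flow_rate < 0) stop("'flow_rate' must be non-negative", call. = FALSE)
  for (nm in c("translation_speed", "mass_loading", "passes", "pitch",
               "stencil_side", "tablet_diameter", "plume_sigma",
               "deposition_efficiency", "radius_coef", "radius_sdlog")) {
    check_positive(get(nm), nm)
  }
  if (passes * pitch > stencil_side + 1e-9) {
    stop("passes * pitch must not exceed stencil_side", call. = FALSE)
  }
  if (stencil_side > tablet_diameter) {
    stop("stencil window cannot be larger than the tablet", call. = FALSE)
  }
  structure(
    list(
      flow_rate = flow_rate, translation_speed = translation_speed,
      mass_loading = mass_loading, passes = as.integer(passes),
      pitch = pitch, stencil_side = stencil_side,
      tablet_diameter = tablet_diameter, plume_sigma = plume_sigma,
      deposition_efficiency = deposition_efficiency,
      radius_coef = radius_coef, radius_exponent = radius_exponent,
      radius_sdlog = radius_sdlog, seed = as.integer(seed)
    ),
    class = "spray_config"
  )
}

#' @export
print.spray_config <- function(x, ...) {
  cat("Electrospray configuration\n")
  cat(sprintf("  flow rate:         %g uL/min\n", x$flow_rate))
  cat(sprintf("  translation speed: %g mm/s\n", x$translation_speed))
  cat(sprintf("  mass loading:      %g wt%%\n", x$mass_loading))
  cat(sprintf("  raster:            %d passes, %g mm pitch, %g mm stencil\n",
              x$passes, x$pitch, x$stencil_side))
  cat(sprintf("  tablet diameter:   %g mm, seed %d\n", x$tablet_diameter,
              x$seed))
  invisible(x)
}

#' Draw a stochastic spot pattern from a spray configuration
#'
#' Deposition is modeled as an inhomogeneous (here piecewise-homogeneous)
#' Poisson process along the zig-zag translation path. The expected number
#' of spots per mm of path is
#' \code{deposition_efficiency * flow_rate / translation_speed}; spot
#' centers sit on the path plus a lateral Gaussian offset with standard
#' deviation \code{plume_sigma}, clipped to the stencil window. Spot radii
#' are lognormal with median \code{radius_coef * flow_rate^radius_exponent};
#' stain opacity scales with dye mass loading (with a small multiplicative
#' jitter) and does not affect geometry, so two configurations differing
#' only in \code{mass_loading} yield identical spot counts and positions
#' for the same seed.
#'
#' Coordinates are in mm relative to the lower-left corner of the stencil
#' window.
#'
#' @param config a [spray_config()].
#' @return an object of class \code{spot_list}: a list with element
#'   \code{spots}, a data frame with columns \code{x}, \code{y} (mm),
#'   \code{radius} (mm) and \code{opacity} (0-1), plus the generating
#'   configuration.
#' @export
sample_spots <- function(config) {
  stopifnot(inherits(config, "spray_config"))
  path_length <- config$passes * config$stencil_side
  rate_per_mm <- config$deposition_efficiency * config$flow_rate /
    config$translation_speed
  spots <- withr::with_seed(config$seed, {
    n <- rpois(1L, rate_per_mm * path_length)
    if (n == 0L) {
      data.frame(x = numeric(0), y = numeric(0), radius = numeric(0),
                 opacity = numeric(0))
    } else {
      s <- runif(n, 0, path_length)                 # arc length along path
      pass_idx <- pmin(floor(s / config$stencil_side), config$passes - 1L)
      along <- s - pass_idx * config$stencil_side
      # alternate direction every pass (zig-zag)
      x_path <- ifelse(pass_idx %% 2 == 0, along, config$stencil_side - along)
      y_path <- (pass_idx + 0.5) * config$pitch
      lat <- rnorm(n, 0, config$plume_sigma)
      x <- x_path + rnorm(n, 0, config$plume_sigma)
      y <- y_path + lat
      # clip to the stencil window (the stencil blocks overspray)
      x <- pmin(pmax(x, 0), config$stencil_side)
      y <- pmin(pmax(y, 0), config$stencil_side)
      med_r <- config$radius_coef * config$flow_rate^config$radius_exponent
      radius <- rlnorm(n, meanlog = log(med_r), sdlog = config$radius_sdlog)
      opacity <- clamp01(0.45 * config$mass_loading * runif(n, 0.85, 1))
      data.frame(x = x, y = y, radius = radius, opacity = opacity)
    }
  })
  structure(list(spots = spots, config = config), class = "spot_list")
}

#' @export
print.spot_list <- function(x, ...) {
  cat(sprintf("Spot pattern: %d spots in a %g x %g mm stencil window\n",
              nrow(x$spots), x$config$stencil_side, x$config$stencil_side))
  if (nrow(x$spots) > 0L) {
    cat(sprintf("  median radius %.3f mm, mean opacity %.2f\n",
                stats::median(x$spots$radius), mean(x$spots$opacity)))
  }
  invisible(x)
}
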