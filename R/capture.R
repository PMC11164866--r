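#' Cellphone-like capture configuration
#'
#' Describes the perturbations applied to a rendered tablet image to mimic
#' a point-of-care cellphone photograph: off-axis camera tilt (modeled as a
#' homography of the tablet plane), in-plane rotation, resampling to a
#' different resolution, defocus blur, sensor noise, and exposure
#' (mean-brightness) changes.
#'
#' @param rotation in-plane rotation, degrees.
#' @param tilt camera tilt off the orthogonal axis, degrees; the modeled
#'   range is 0-60 (patterns photographed beyond ~45 degrees deform too much
#'   to authenticate reliably).
#' @param brightness_target desired mean 8-bit brightness of the output
#'   (cellphone exposures typically land between 130 and 200); \code{NA}
#'   leaves brightness untouched.
#' @param blur_sigma Gaussian blur sigma, px; 0 disables.
#' @param output_resolution output image side, px (square); minimum 256;
#'   \code{NA} keeps the input resolution.
#' @param noise_sigma additive Gaussian noise sigma on the 8-bit intensity
#'   scale; 0 disables.
#' @param seed integer RNG seed controlling the random tilt axis and the
#'   noise realisation.
#' @return an object of class \code{capture_config}.
#' @seealso [perturb_capture()]
#' @export
capture_config <- function(rotation = 0, tilt = 0, brightness_target = NA,
                           blur_sigma = 0, output_resolution = NA,
                           noise_sigma = 0, seed = 1L) {
  if (!is.numeric(tilt) || tilt < 0 || tilt > 60) {
    stop("tilt must be in [0, 60] degrees (out of modeled range)",
         call. = FALSE)
  }
  if (!is.na(output_resolution) && output_resolution < 256) {
    stop("output_resolution must be at least 256 px", call. = FALSE)
  }
  if (blur_sigma < 0 || noise_sigma < 0) {
    stop("blur_sigma and noise_sigma must be non-negative", call. = FALSE)
  }
  if (!is.na(brightness_target) &&
      (brightness_target <= 0 || brightness_target > 255)) {
    stop("brightness_target must be in (0, 255]", call. = FALSE)
  }
  structure(
    list(rotation = rotation, tilt = tilt,
         brightness_target = brightness_target, blur_sigma = blur_sigma,
         output_resolution = output_resolution, noise_sigma = noise_sigma,
         seed = as.integer(seed)),
    class = "capture_config"
  )
}

#' @export
print.capture_config <- function(x, ...) {
  cat(sprintf(paste0("Capture: rotation %g deg, tilt %g deg, brightness %s, ",
                     "blur %g px, resolution %s, noise %g, seed %d\n"),
              x$rotation, x$tilt,
              ifelse(is.na(x$brightness_target), "as-is",
                     as.character(x$brightness_target)),
              x$blur_sigma,
              ifelse(is.na(x$output_resolution), "as-is",
                     as.character(x$output_resolution)),
              x$noise_sigma, x$seed))
  invisible(x)
}

# Rodrigues rotation about an in-plane axis (angle phi in the image plane)
# by the tilt angle theta; returns the 3x3 rotation matrix.
rotation_about_inplane_axis <- function(phi_deg, theta_deg) {
  phi <- phi_deg * pi / 180
  th <- theta_deg * pi / 180
  u <- c(cos(phi), sin(phi), 0)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Forward homography (0-based centered pixel coords in -> out) for a camera
# tilt of `theta` about an in-plane axis at angle `phi`, using a simple
# perspective camera with focal length `f` px.
tilt_homography <- function(phi_deg, theta_deg, f) {
  R <- rotation_about_inplane_axis(phi_deg, theta_deg)
  matrix(c(f * R[1, 1], f * R[2, 1], R[3, 1],
           f * R[1, 2], f * R[2, 2], R[3, 2],
           0, 0, f), 3, 3)
}

rotation_homography <- function(psi_deg) {
  psi <- psi_deg * pi / 180
  matrix(c(cos(psi), sin(psi), 0, -sin(psi), cos(psi), 0, 0, 0, 1), 3, 3)
}

translation_homography <- function(tx, ty) {
  matrix(c(1, 0, 0, 0, 1, 0, tx, ty, 1), 3, 3)
}

# Exact 90-degree rotation (counter-clockwise in array coordinates),
# channel-wise, no interpolation.
rot90_array <- function(a, times) {
  times <- ((times %% 4) + 4) %% 4
  if (times == 0) return(a)
  rot_once <- function(m) {
    m2 <- t(m)
    m2[, rev(seq_len(ncol(m2))), drop = FALSE]
  }
  for (k in seq_len(times)) {
    if (length(dim(a)) == 2L) {
      a <- rot_once(a)
    } else {
      d <- dim(a)
      out <- array(0, dim = c(d[2L], d[1L], d[3L]))
      for (ch in seq_len(d[3L])) out[, , ch] <- rot_once(a[, , ch])
      a <- out
    }
  }
  a
}

#' Apply cellphone-like perturbations to a tablet image
#'
#' Perturbations are applied in a fixed order: projective tilt about a
#' random in-plane axis, in-plane rotation, resampling to the output
#' resolution, Gaussian blur, additive Gaussian noise, and finally an
#' affine intensity rescale bringing the mean brightness to the target.
#' All randomness (tilt axis direction, noise) is driven by the
#' configuration seed, so the result is reproducible. An identity
#' configuration returns the input unchanged, and rotations that are exact
#' multiples of 90 degrees (with zero tilt) are performed without
#' interpolation.
#'
#' @param image an image (path, \code{EBImage::Image}, or array).
#' @param config a [capture_config()].
#' @return an \code{EBImage::Image} in color mode.
#' @export
perturb_capture <- function(image, config) {
  stopifnot(inherits(config, "capture_config"))
  a <- as_rgb_array(image)
  withr::with_seed(config$seed, {
    w <- dim(a)[1L]
    h <- dim(a)[2L]
    if (config$tilt == 0 && config$rotation %% 90 == 0) {
      if (config$rotation %% 360 != 0) {
        a <- rot90_array(a, config$rotation %/% 90)
      }
    } else {
      phi <- runif(1, 0, 360)
      f <- 2 * max(w, h)
      H <- translation_homography((w - 1) / 2, (h - 1) / 2) %*%
        rotation_homography(config$rotation) %*%
        tilt_homography(phi, config$tilt, f) %*%
        translation_homography(-(w - 1) / 2, -(h - 1) / 2)
      a <- warp_image(a, solve(H), w, h, bg = BACKGROUND_COLOR)
    }
    if (!is.na(config$output_resolution) &&
        (dim(a)[1L] != config$output_resolution ||
         dim(a)[2L] != config$output_resolution)) {
      img <- EBImage::Image(a, colormode = "Color")
      img <- EBImage::resize(img, w = config$output_resolution,
                             h = config$output_resolution)
      a <- EBImage::imageData(img)
    }
    if (config$blur_sigma > 0) {
      img <- EBImage::gblur(EBImage::Image(a, colormode = "Color"),
                            sigma = config$blur_sigma)
      a <- EBImage::imageData(img)
    }
    if (config$noise_sigma > 0) {
      a <- a + array(rnorm(length(a), 0, config$noise_sigma / 255), dim(a))
      a <- clamp01(a)
    }
    if (!is.na(config$brightness_target)) {
      # exposure gain so the mean 8-bit brightness of the subject (the
      # tablet, i.e. pixels well above the dark background) hits the
      # target; measured on the subject because the synthetic background
      # is deliberately dark, which a whole-frame mean would conflate
      # with the exposure of the tablet itself
      target <- config$brightness_target / 255
      lum <- luma601(a)
      subject <- lum > 0.35
      cur <- if (any(subject)) mean(lum[subject]) else mean(lum)
      if (cur > 0) {
        gain_of <- function(g) {
          lg <- clamp01(a * g)
          lumg <- luma601(lg)
          if (any(subject)) mean(lumg[subject]) else mean(lumg)
        }
        lo <- 0
        hi <- target / cur
        while (gain_of(hi) < target - 1 / 512 && hi < 64) hi <- hi * 2
        for (it in 1:12) {
          mid <- (lo + hi) / 2
          if (gain_of(mid) < target) lo <- mid else hi <- mid
        }
        a <- clamp01(a * (lo + hi) / 2)
      }
    }
  })
  EBImage::Image(a, colormode = "Color")
}
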