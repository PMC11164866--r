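# Rasterisation of a simulated deposit onto a tablet image.

# Dye transmission per unit opacity: a carmine-like red (strong absorption
# in green/blue). Stains compound multiplicatively where spots overlap.
CARMINE_TRANSMISSION <- c(0.60, 0.06, 0.18)

# Antacid tablets are near-white and spectrally neutral, so the tablet body
# carries almost no saturation; this keeps Otsu on the saturation channel
# bimodal (stain vs everything else).
TABLET_COLOR <- c(0.93, 0.92, 0.91)
BACKGROUND_COLOR <- c(0.16, 0.16, 0.16)

#' Render a spot pattern onto a synthetic tablet image
#'
#' Draws a near-white circular tablet on a dark neutral background and
#' rasterises each spot as a soft-edged red stain. Stain color is
#' carmine-like (deep red); spot opacity scales the amount of dye, and
#' overlapping spots compound multiplicatively, so double deposits are
#' darker. The output is deterministic given its inputs.
#'
#' The canvas is a square 1.25 times the tablet diameter; the stencil
#' window (and so the spot coordinate origin) is centered on the tablet.
#'
#' @param spots a [sample_spots()] result (class \code{spot_list}).
#' @param config the [spray_config()] describing tablet and stencil
#'   geometry; defaults to the configuration stored in \code{spots}.
#' @param px_per_mm raster resolution, pixels per mm.
#' @return an \code{EBImage::Image} in color mode, values in [0, 1].
#' @export
render_tablet <- function(spots, config = spots$config, px_per_mm = 30) {
  stopifnot(inherits(spots, "spot_list"), inherits(config, "spray_config"))
  check_positive(px_per_mm, "px_per_mm")
  side_mm <- config$tablet_diameter * 1.25
  n <- max(32L, as.integer(round(side_mm * px_per_mm)))
  cx <- (n - 1) / 2
  xs <- matrix(0:(n - 1), n, n)
  ys <- t(xs)
  rr <- sqrt((xs - cx)^2 + (ys - cx)^2)
  tablet <- rr <= config$tablet_diameter / 2 * px_per_mm
  # soft 1 px antialiased rim
  rim <- clamp01(config$tablet_diameter / 2 * px_per_mm - rr + 0.5)
  img <- array(0, dim = c(n, n, 3L))
  for (ch in 1:3) {
    img[, , ch] <- BACKGROUND_COLOR[ch] +
      rim * (TABLET_COLOR[ch] - BACKGROUND_COLOR[ch])
  }
  sp <- spots$spots
  if (nrow(sp) > 0L) {
    origin <- cx - config$stencil_side / 2 * px_per_mm  # window corner, px
    edge <- 0.6  # px, width of the soft spot edge
    for (i in seq_len(nrow(sp))) {
      scx <- origin + sp$x[i] * px_per_mm
      scy <- origin + sp$y[i] * px_per_mm
      r_px <- sp$radius[i] * px_per_mm
      x0 <- max(0L, floor(scx - r_px - 2))
      x1 <- min(n - 1L, ceiling(scx + r_px + 2))
      y0 <- max(0L, floor(scy - r_px - 2))
      y1 <- min(n - 1L, ceiling(scy + r_px + 2))
      if (x1 < x0 || y1 < y0) next
      bx <- (x0:x1)
      by <- (y0:y1)
      dist <- sqrt(outer((bx - scx)^2, (by - scy)^2, `+`))
      m <- sp$opacity[i] * clamp01((r_px - dist) / edge + 0.5)
      for (ch in 1:3) {
        img[bx + 1L, by + 1L, ch] <- img[bx + 1L, by + 1L, ch] *
          (1 - m * (1 - CARMINE_TRANSMISSION[ch]))
      }
    }
  }
  EBImage::Image(clamp01(img), colormode = "Color")
}
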