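# Pattern extraction: raw tablet photo -> cropped grayscale ePUF pattern.
#
# The chain is (1) locate the pill by Otsu thresholding the HSV value
# channel and keeping the largest connected component, (2) crop to the pill
# and blank the background, (3) Otsu threshold the saturation channel to
# segment the dyed spots, fit a minimum-area rotated rectangle to them, and
# rotate/crop the image to that rectangle, converting to grayscale
# (ITU-R BT.601 luma). HSV follows the base-R convention: all three
# channels on [0, 1], hue as a fraction of the circle.

#' Locate the pill in a raw tablet photograph
#'
#' Converts the image to HSV, applies automatic Otsu thresholding to the
#' value (brightness) channel, and keeps the largest connected foreground
#' component as the pill.
#'
#' @param raw a color image (path, \code{EBImage::Image}, or array).
#' @return a list with \code{mask} (logical matrix, pill pixels TRUE) and
#'   \code{rect}, the axis-aligned bounding rectangle as a list of 1-based
#'   inclusive index ranges \code{x} and \code{y}.
#' @export
locate_pill <- function(raw) {
  a <- as_rgb_array(raw)
  v <- hsv_channels(a)$v
  th <- otsu_threshold(v)
  fg <- v > th
  if (sum(fg) < 0.01 * length(fg)) {
    stop("no pill found (foreground below 1% of frame)", call. = FALSE)
  }
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg * 1)))
  tab <- tabulate(labels[labels > 0])
  mask <- labels == which.max(tab)
  idx <- which(mask, arr.ind = TRUE)
  list(
    mask = mask,
    rect = list(x = range(idx[, 1L]), y = range(idx[, 2L]))
  )
}

#' Crop to the pill and blank the background
#'
#' Crops the image to the pill bounding rectangle and sets every pixel
#' outside the pill mask (within the crop) to black.
#'
#' @param raw the color image given to [locate_pill()].
#' @param mask logical pill mask over the full frame.
#' @param rect bounding rectangle (as returned by [locate_pill()]).
#' @return a color array cropped to \code{rect} with the background blanked.
#' @export
crop_and_blank <- function(raw, mask, rect) {
  a <- as_rgb_array(raw)
  if (length(rect$x) != 2L || length(rect$y) != 2L ||
      rect$x[1L] < 1L || rect$y[1L] < 1L ||
      rect$x[2L] > dim(a)[1L] || rect$y[2L] > dim(a)[2L] ||
      rect$x[1L] > rect$x[2L] || rect$y[1L] > rect$y[2L]) {
    stop("invalid crop rectangle", call. = FALSE)
  }
  xs <- rect$x[1L]:rect$x[2L]
  ys <- rect$y[1L]:rect$y[2L]
  cropped <- a[xs, ys, , drop = FALSE]
  m <- mask[xs, ys]
  for (ch in 1:3) cropped[, , ch] <- cropped[, , ch] * m
  cropped
}

# Minimum-area enclosing rectangle of a 2-column point matrix (rotating
# calipers over the convex hull). Returns the rectangle angle (degrees) and
# the point ranges in the rotated frame.
min_area_rect <- function(pts) {
  if (nrow(pts) < 3L) {
    return(list(angle = 0,
                xr = range(pts[, 1L]), yr = range(pts[, 2L])))
  }
  hull <- pts[chull(pts), , drop = FALSE]
  nh <- nrow(hull)
  best <- NULL
  best_area <- Inf
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    if (all(e == 0)) next
    ang <- atan2(e[2L], e[1L])
    R <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2L, 2L)
    rot <- hull %*% t(R)  # rotate points by -ang
    w <- diff(range(rot[, 1L]))
    h <- diff(range(rot[, 2L]))
    if (w * h < best_area) {
      best_area <- w * h
      best <- list(angle = ang * 180 / pi, xr = range(rot[, 1L]),
                   yr = range(rot[, 2L]))
    }
  }
  best %||% list(angle = 0, xr = range(pts[, 1L]), yr = range(pts[, 2L]))
}

#' Extract the ePUF pattern from a cropped, background-blanked pill image
#'
#' Otsu-thresholds the saturation channel to segment the dyed spots, fits a
#' minimum-area (rotated) rectangle to the spot pixels, rotates the image so
#' the rectangle is axis-aligned (canonicalised to width >= height; the
#' residual 180-degree ambiguity is harmless because SIFT descriptors are
#' rotation-invariant), crops to it, and converts to grayscale.
#'
#' A saturation sanity check guards the degenerate blank-tablet case: if the
#' segmented "pattern" is essentially unsaturated there is no dye on the
#' tablet and extraction fails.
#'
#' @param cropped output of [crop_and_blank()].
#' @param source_id identifier carried into the result.
#' @return an object of class \code{pattern_image}: list with
#'   \code{pixels} (grayscale matrix in [0, 1]), \code{source_id}, and
#'   \code{provenance} (rotation angle and crop rectangle applied).
#' @export
extract_pattern <- function(cropped, source_id = NA_character_) {
  a <- as_rgb_array(cropped)
  hsv <- hsv_channels(a)
  s <- hsv$s
  th <- otsu_threshold(s)
  mask <- s > th
  # degenerate-input guard: a genuine dye pattern is clearly more saturated
  # than the bare (near-neutral) tablet surface, even in overexposed
  # captures; a blank tablet yields a low-contrast, low-saturation split
  pill <- hsv$v > 0.05
  rest <- pill & !mask
  if (sum(mask) < 30L || mean(s[mask]) < 0.08 ||
      (sum(rest) > 0L && mean(s[mask]) < 3 * mean(s[rest]))) {
    stop("no pattern found (tablet appears blank)", call. = FALSE)
  }
  pts <- which(mask, arr.ind = TRUE) - 1  # 0-based pixel centers
  mar <- min_area_rect(pts)
  if (diff(mar$yr) > diff(mar$xr)) {  # canonicalise: width >= height
    ang <- (mar$angle + 90) * pi / 180
    R <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2L, 2L)
    hull <- pts[chull(pts), , drop = FALSE]
    rot <- hull %*% t(R)
    mar <- list(angle = ang * 180 / pi, xr = range(rot[, 1L]),
                yr = range(rot[, 2L]))
  }
  pad <- 2
  out_w <- as.integer(round(diff(mar$xr))) + 1L + 2L * as.integer(pad)
  out_h <- as.integer(round(diff(mar$yr))) + 1L + 2L * as.integer(pad)
  if (min(out_w, out_h) < 32L) {
    stop("no pattern found (pattern region too small)", call. = FALSE)
  }
  # output (u, v) -> input p = R(theta) %*% (q0 + (u, v))
  theta <- mar$angle * pi / 180
  Rt <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
  q0 <- c(mar$xr[1L] - pad, mar$yr[1L] - pad)
  t0 <- Rt %*% q0
  H_inv <- rbind(cbind(Rt, t0), c(0, 0, 1))
  warped <- warp_image(a, H_inv, out_w, out_h, bg = 0)
  structure(
    list(
      pixels = luma601(warped),
      source_id = source_id,
      provenance = list(angle = mar$angle,
                        rect = list(x = mar$xr, y = mar$yr), pad = pad)
    ),
    class = "pattern_image"
  )
}

#' @export
print.pattern_image <- function(x, ...) {
  cat(sprintf("ePUF pattern image '%s': %d x %d px (8-bit-equivalent range)\n",
              x$source_id %||% NA, dim(x$pixels)[1L], dim(x$pixels)[2L]))
  invisible(x)
}

#' Full pattern-extraction pipeline
#'
#' Composition of [locate_pill()], [crop_and_blank()] and
#' [extract_pattern()], in that order. Optionally writes the two
#' intermediate images and the final pattern as PNGs (suffixes
#' \code{_step1}, \code{_step2}, \code{_step3}) for debugging.
#'
#' @param raw image path, \code{EBImage::Image} or array.
#' @param source_id identifier for the extracted pattern; defaults to the
#'   file name when \code{raw} is a path.
#' @param debug_prefix if non-\code{NULL}, a path prefix for the three
#'   intermediate PNGs.
#' @return a \code{pattern_image}.
#' @export
process_image <- function(raw, source_id = NULL, debug_prefix = NULL) {
  if (is.null(source_id)) {
    source_id <- if (is.character(raw)) {
      tools::file_path_sans_ext(basename(raw))
    } else {
      NA_character_
    }
  }
  a <- as_rgb_array(raw)
  pill <- locate_pill(a)
  cropped <- crop_and_blank(a, pill$mask, pill$rect)
  pat <- extract_pattern(cropped, source_id = source_id)
  if (!is.null(debug_prefix)) {
    EBImage::writeImage(EBImage::Image(pill$mask * 1),
                        paste0(debug_prefix, "_step1.png"))
    EBImage::writeImage(EBImage::Image(cropped, colormode = "Color"),
                        paste0(debug_prefix, "_step2.png"))
    EBImage::writeImage(EBImage::Image(clamp01(pat$pixels)),
                        paste0(debug_prefix, "_step3.png"))
  }
  pat
}
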