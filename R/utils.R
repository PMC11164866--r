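# Internal image helpers. Images follow the EBImage layout throughout:
# arrays with dim = (x, y) or (x, y, 3), values in [0, 1].

# Coerce an input (path / EBImage Image / plain array) to a color array.
as_rgb_array <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("image file not found: ", x, call. = FALSE)
    img <- tryCatch(
      EBImage::readImage(x),
      error = function(e) {
        stop("failed to read image '", x, "': ", conditionMessage(e),
             call. = FALSE)
      }
    )
    x <- img
  }
  a <- if (inherits(x, "Image")) EBImage::imageData(x) else x
  if (!is.numeric(a)) stop("image must be numeric", call. = FALSE)
  d <- dim(a)
  if (is.null(d) || length(d) < 2L) stop("not an image array", call. = FALSE)
  if (length(d) == 2L) a <- array(rep(a, 3L), dim = c(d, 3L))
  if (dim(a)[3L] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  a
}

as_gray_matrix <- function(x) {
  a <- if (inherits(x, "Image")) EBImage::imageData(x) else x
  d <- dim(a)
  if (length(d) == 2L) return(a)
  luma601(a)
}

# ITU-R BT.601 luma weights
luma601 <- function(rgb) {
  0.299 * rgb[, , 1L] + 0.587 * rgb[, , 2L] + 0.114 * rgb[, , 3L]
}

# HSV channels of a color array; base-R convention, all channels in [0, 1]
# (hue as a fraction of the full circle). Black pixels get S = 0.
hsv_channels <- function(rgb) {
  d <- dim(rgb)
  m <- rbind(as.vector(rgb[, , 1L]), as.vector(rgb[, , 2L]),
             as.vector(rgb[, , 3L]))
  m <- pmin(pmax(m, 0), 1)
  hsv <- rgb2hsv(m, maxColorValue = 1)
  list(
    h = matrix(hsv[1L, ], d[1L], d[2L]),
    s = matrix(hsv[2L, ], d[1L], d[2L]),
    v = matrix(hsv[3L, ], d[1L], d[2L])
  )
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Otsu threshold of a [0,1] matrix (EBImage implementation).
otsu_threshold <- function(m) {
  EBImage::otsu(EBImage::Image(clamp01(m)), range = c(0, 1))
}

# Apply a 3x3 homography (inverse map: output coords -> input coords) to an
# image array; 0-based pixel-center convention on both sides.
warp_image <- function(img, H_inv, out_w, out_h, bg = 0) {
  a <- if (inherits(img, "Image")) EBImage::imageData(img) else img
  nch <- if (length(dim(a)) == 3L) dim(a)[3L] else 1L
  bg <- rep_len(bg, nch)
  .warp_cpp(a, H_inv, as.integer(out_w), as.integer(out_h), bg)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_positive <- function(value, name) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value <= 0) {
    stop(sprintf("'%s' must be a single positive number", name),
         call. = FALSE)
  }
  invisible(value)
}
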