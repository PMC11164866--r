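# Ground truth for segmentation tests comes from the simulator geometry:
# the tablet disk and the stencil window are known exactly.

render_with_truth <- function(seed = 21, px_per_mm = 30) {
  cfg <- spray_config(seed = seed)
  spots <- sample_spots(cfg)
  img <- render_tablet(spots, cfg, px_per_mm = px_per_mm)
  n <- dim(img)[1]
  cx <- (n - 1) / 2
  list(img = img, cfg = cfg, spots = spots, n = n, cx = cx,
       px_per_mm = px_per_mm,
       radius_px = cfg$tablet_diameter / 2 * px_per_mm)
}

test_that("locate_pill recovers the tablet disk with IoU >= 0.95", {
  rt <- render_with_truth()
  pill <- locate_pill(rt$img)
  idx_x <- matrix(0:(rt$n - 1), rt$n, rt$n)
  truth <- sqrt((idx_x - rt$cx)^2 + (t(idx_x) - rt$cx)^2) <= rt$radius_px
  iou <- sum(pill$mask & truth) / sum(pill$mask | truth)
  expect_gte(iou, 0.95)
})

test_that("locate_pill fails on an all-black frame", {
  black <- array(0, dim = c(128, 128, 3))
  expect_error(locate_pill(black), "no pill found")
})

test_that("the pill bounding rectangle is translation-equivariant", {
  rt <- render_with_truth()
  a <- EBImage::imageData(rt$img)
  shifted <- array(epuf:::BACKGROUND_COLOR[1], dim = dim(a) + c(40, 40, 0))
  for (ch in 1:3) {
    shifted[, , ch] <- epuf:::BACKGROUND_COLOR[ch]
    shifted[31:(30 + dim(a)[1]), 11:(10 + dim(a)[2]), ch] <- a[, , ch]
  }
  r0 <- locate_pill(a)$rect
  r1 <- locate_pill(shifted)$rect
  expect_equal(r1$x, r0$x + 30)
  expect_equal(r1$y, r0$y + 10)
})

test_that("crop_and_blank zeroes exactly the masked-out pixels", {
  a <- array(runif(20 * 20 * 3, min = 0.2), dim = c(20, 20, 3))
  mask <- matrix(rep(c(TRUE, FALSE), length.out = 400), 20, 20)
  rect <- list(x = c(3L, 18L), y = c(2L, 17L))
  out <- crop_and_blank(a, mask, rect)
  m <- mask[3:18, 2:17]
  for (ch in 1:3) {
    expect_true(all(out[, , ch][!m] == 0))
    expect_identical(out[, , ch][m], a[3:18, 2:17, ch][m])
  }
  # full mask: pure crop
  out2 <- crop_and_blank(a, matrix(TRUE, 20, 20), rect)
  expect_identical(out2, a[3:18, 2:17, , drop = FALSE])
  expect_error(crop_and_blank(a, mask, list(x = c(0L, 25L), y = c(1L, 2L))),
               "rectangle")
})

test_that("extract_pattern recovers the stencil window within 10%", {
  rt <- render_with_truth()
  pat <- process_image(rt$img, source_id = "truth")
  target <- rt$cfg$stencil_side * rt$px_per_mm
  expect_equal(dim(pat$pixels)[1], target, tolerance = 0.1)
  expect_equal(dim(pat$pixels)[2], target, tolerance = 0.1)
})

test_that("a blank tablet has no pattern to extract", {
  cfg <- spray_config(flow_rate = 0, seed = 1)
  img <- render_tablet(sample_spots(cfg), cfg)
  expect_error(process_image(img), "no pattern found")
})

test_that("process_image equals the stepwise composition", {
  rt <- render_with_truth(seed = 22)
  a <- epuf:::as_rgb_array(rt$img)
  pill <- locate_pill(a)
  stepwise <- extract_pattern(crop_and_blank(a, pill$mask, pill$rect))
  direct <- process_image(a)
  expect_identical(direct$pixels, stepwise$pixels)
})

test_that("unreadable image files surface an I/O error naming the path", {
  bad <- file.path(tempdir(), "truncated.png")
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x00)), bad)
  expect_error(process_image(bad), "truncated.png")
})

test_that("a rotated capture still authenticates against its own pattern", {
  rt <- render_with_truth(seed = 23)
  ref_fs <- extract_features(process_image(rt$img, source_id = "truth"))
  q <- perturb_capture(rt$img, capture_config(rotation = 45, tilt = 0,
                                              output_resolution = 480,
                                              seed = 1))
  pat <- process_image(q)
  expect_s3_class(pat, "pattern_image")
  expect_true(all(dim(pat$pixels) >= 32))
  # the de-rotated extraction must remain prominently matchable
  db <- c(tiny_db()$features, list(truth = ref_fs))
  v <- decide(count_matches(extract_features(pat), db, k = 0.7,
                            symmetry = TRUE), match_config())
  expect_identical(v$outcome, "confident")
  expect_identical(v$best_id, "truth")
})

test_that("nearly all ground-truth spot pixels land inside the final crop", {
  rt <- render_with_truth(seed = 24)
  pat <- process_image(rt$img)
  prov <- pat$provenance
  theta <- prov$angle * pi / 180
  # same rotate-by-minus-theta convention as the extraction module, in the
  # coordinates of the pill crop (the frame extract_pattern works in)
  Rm <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
  pill_rect <- locate_pill(rt$img)$rect
  origin <- rt$cx - rt$cfg$stencil_side / 2 * rt$px_per_mm
  pts <- cbind(origin + rt$spots$spots$x * rt$px_per_mm -
                 (pill_rect$x[1] - 1),
               origin + rt$spots$spots$y * rt$px_per_mm -
                 (pill_rect$y[1] - 1))
  q <- pts %*% t(Rm)  # rotate spot centers into the crop frame
  inside <- q[, 1] >= prov$rect$x[1] - prov$pad - 1 &
    q[, 1] <= prov$rect$x[2] + prov$pad + 1 &
    q[, 2] >= prov$rect$y[1] - prov$pad - 1 &
    q[, 2] <= prov$rect$y[2] + prov$pad + 1
  expect_gte(mean(inside), 0.99)
})

test_that("the crop rectangle is stable under uniform brightness scaling", {
  rt <- render_with_truth(seed = 25)
  a <- epuf:::as_rgb_array(rt$img)
  crop_mask <- function(img) {
    pat <- process_image(img)
    prov <- pat$provenance
    theta <- prov$angle * pi / 180
    Rm <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
    pill_rect <- locate_pill(img)$rect
    n <- dim(epuf:::as_rgb_array(img))[1]
    grid <- cbind(rep(0:(n - 1), n) - (pill_rect$x[1] - 1),
                  rep(0:(n - 1), each = n) - (pill_rect$y[1] - 1))
    q <- grid %*% t(Rm)
    m <- q[, 1] >= prov$rect$x[1] & q[, 1] <= prov$rect$x[2] &
      q[, 2] >= prov$rect$y[1] & q[, 2] <= prov$rect$y[2]
    matrix(m, n, n)
  }
  m1 <- crop_mask(a)
  for (scale in c(0.7, 1.3)) {
    m2 <- crop_mask(epuf:::clamp01(a * scale))
    iou <- sum(m1 & m2) / sum(m1 | m2)
    expect_gte(iou, 0.9)
  }
})

test_that("re-embedding an extracted pattern on a fresh tablet is recoverable", {
  # extraction idempotence, checked through the full matching stack: take
  # an extracted pattern, paint it back onto a clean synthetic tablet as a
  # red stain, re-run extraction, and demand a prominent self-match
  rt <- render_with_truth(seed = 26)
  pat <- process_image(rt$img, source_id = "orig")
  fs <- extract_features(pat)
  g <- pat$pixels
  n <- 600
  canvas <- array(0, dim = c(n, n, 3))
  cx <- (n - 1) / 2
  xs <- matrix(0:(n - 1), n, n)
  disk <- sqrt((xs - cx)^2 + (t(xs) - cx)^2) <= 240
  tablet <- epuf:::TABLET_COLOR
  trans <- epuf:::CARMINE_TRANSMISSION
  m <- pmin(pmax((tablet[2] - g) / 0.6, 0), 1)  # stain mass from darkness
  x0 <- floor((n - dim(g)[1]) / 2)
  y0 <- floor((n - dim(g)[2]) / 2)
  for (ch in 1:3) {
    plane <- matrix(epuf:::BACKGROUND_COLOR[ch], n, n)
    plane[disk] <- tablet[ch]
    patch <- tablet[ch] * (1 - m * (1 - trans[ch]))
    plane[x0 + seq_len(dim(g)[1]), y0 + seq_len(dim(g)[2])] <- patch
    canvas[, , ch] <- plane
  }
  re_pat <- process_image(canvas, source_id = "reembedded")
  re_fs <- extract_features(re_pat)
  db <- c(tiny_db()$features, list(orig = fs))
  v <- decide(count_matches(re_fs, db, k = 0.7, symmetry = TRUE),
              match_config())
  expect_identical(v$best_id, "orig")
  expect_gte(v$prominence, 0.9)
})
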