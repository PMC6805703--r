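# Per-slice imaging pipeline: decode, filter, segment, split, classify.

rgb_canvas <- function(h, w, color = c(255, 255, 255)) {
  px <- array(0, dim = c(h, w, 3))
  for (k in 1:3) px[, , k] <- color[k]
  px
}

paint_rect <- function(px, rows, cols, color) {
  for (k in 1:3) px[rows, cols, k] <- color[k]
  px
}

test_that("image decoding handles RGB, grayscale, 16-bit and alpha", {
  # plain white PNG decodes to all-255 channels
  f <- tempfile(fileext = ".png")
  png::writePNG(array(1, dim = c(64, 64, 3)), f)
  img <- load_slice_image(f, 1)
  expect_s3_class(img, "slice_image")
  expect_true(all(img$pixels == 255))
  expect_identical(img$slice_index, 1L)

  # grayscale is promoted to RGB
  png::writePNG(matrix(0.5, 32, 32), f)
  g <- load_slice_image(f, 2)
  expect_equal(dim(g$pixels), c(32, 32, 3))
  expect_true(all(g$pixels == round(0.5 * 255)))

  # 16-bit TIFF: constant mid-gray maps onto the 0-255 scale
  ft <- tempfile(fileext = ".tiff")
  tiff::writeTIFF(matrix(0.5, 24, 24), ft, bits.per.sample = 16L)
  t16 <- load_slice_image(ft, 3)
  expect_lte(max(abs(t16$pixels - 127.5)), 0.5)  # one 8-bit level of 0.5

  # RGBA with a fully transparent border composites onto white
  rgba <- array(0, dim = c(20, 20, 4))
  rgba[, , 1] <- 1                       # red, fully...
  rgba[, , 4] <- 0                       # ...transparent
  rgba[5:16, 5:16, 4] <- 1               # opaque red center
  png::writePNG(rgba, f)
  a <- load_slice_image(f, 4)
  expect_true(all(a$pixels[1, 1, ] == c(255, 255, 255)))   # border -> white
  expect_true(all(a$pixels[10, 10, ] == c(255, 0, 0)))     # center kept
  # manual compositing of a half-transparent pixel
  rgba[1, 1, ] <- c(1, 0, 0, 0.5)
  png::writePNG(rgba, f)
  a2 <- load_slice_image(f, 5)
  # manual composite, allowing one level for the stored-alpha quantization
  expect_lte(max(abs(as.vector(a2$pixels[1, 1, ]) -
                       c(255, 127.5, 127.5))), 1)

  expect_error(load_slice_image(tempfile(fileext = ".png"), 1), "not found")
  bad <- tempfile(fileext = ".png")
  writeLines("not a png", bad)
  expect_error(load_slice_image(bad, 1), "decode")
})

test_that("channel mixing and luminance conversion follow the stated weights", {
  px <- rgb_canvas(16, 16, c(0, 0, 255))
  px[1, 1, ] <- c(255, 0, 0)
  px[1, 2, ] <- c(60, 60, 200)
  px[1, 3, ] <- c(255, 255, 255)
  img <- slice_image(px, 1)

  blue <- apply_blue_filter(img)
  expect_equal(blue[2, 2], 1.0)             # pure blue -> bright
  expect_equal(blue[1, 1], 0.0)             # pure red -> dark
  expect_equal(blue[1, 2], 200 / 255)

  lum <- to_grayscale(img)
  expect_equal(lum[1, 3], 1.0)
  expect_equal(lum[2, 2], 0.114)
  expect_equal(lum[1, 1], 0.299)

  # negative mixer weights are allowed within [-2, 2]; clamping applies
  neg <- apply_blue_filter(img, c(-1, 0, 1))
  expect_equal(neg[1, 1], 0)                # -255 clamps to 0
  expect_error(apply_blue_filter(img, c(0, 0, 3)), "\\[-2, 2\\]")
  expect_error(apply_blue_filter(img, c(0, NA, 1)), "finite")
})

test_that("tissue segmentation removes debris and fills interior pallor", {
  px <- paint_rect(rgb_canvas(64, 64), 13:52, 13:52, c(190, 40, 40))
  img <- slice_image(px, 1)
  m <- segment_tissue(img)
  expect_equal(area_px(m), 1600)

  expect_error(segment_tissue(slice_image(rgb_canvas(64, 64), 1)),
               "no tissue detected")

  # 3-px speck far from the square is dropped at min_object_px = 10
  px2 <- paint_rect(px, 60, 60:62, c(190, 40, 40))
  m2 <- segment_tissue(slice_image(px2, 1), min_object_px = 10)
  expect_equal(area_px(m2), 1600)
  m3 <- segment_tissue(slice_image(px2, 1), min_object_px = 0)
  expect_equal(area_px(m3), 1603)

  # near-white interior hole (infarct-like pallor) is filled back in
  px3 <- paint_rect(px, 30:35, 30:35, c(250, 250, 250))
  m4 <- segment_tissue(slice_image(px3, 1))
  expect_equal(area_px(m4), 1600)
})

test_that("hemisphere split conserves area, honors orientation and midline", {
  px <- paint_rect(rgb_canvas(64, 64), 13:52, 13:52, c(190, 40, 40))
  m <- segment_tissue(slice_image(px, 1))

  sp <- split_hemispheres(m)
  expect_equal(area_px(sp$left), area_px(sp$right))          # symmetric
  expect_equal(area_px(sp$left) + area_px(sp$right), area_px(m))

  fl <- split_hemispheres(m, "flipped")
  expect_equal(area_px(fl$left), area_px(sp$right))

  # asymmetric mask: conservation and flip involution
  px2 <- paint_rect(px, 20:45, 53:60, c(190, 40, 40))
  ma <- segment_tissue(slice_image(px2, 1))
  spa <- split_hemispheres(ma)
  expect_equal(area_px(spa$left) + area_px(spa$right), area_px(ma))
  mirrored <- tissue_mask(unclass(ma)[, 64:1])
  spm <- split_hemispheres(mirrored, "flipped")
  expect_equal(area_px(spm$left), area_px(spa$left))
  expect_equal(area_px(spm$right), area_px(spa$right))

  # explicit midline and its error modes
  spx <- split_hemispheres(m, midline = 20.5)
  expect_equal(area_px(spx$left), 40 * 8)
  expect_error(split_hemispheres(m, midline = 200), "outside")
  expect_error(split_hemispheres(m, midline = 5), "degenerate")
})

test_that("otsu matches exhaustive search and degenerates safely", {
  # bimodal half/half: bright half is classified exactly
  vals <- c(rep(0.1, 200), rep(0.9, 200))
  gray <- matrix(vals, 20, 20)
  tis <- tissue_mask(matrix(TRUE, 20, 20))
  ci <- classify_infarct(gray, tis)
  expect_equal(sum(ci$mask), 200)
  expect_false(ci$flagged)
  expect_true(ci$threshold > 0.1 && ci$threshold <= 0.9)

  # oracle equivalence on random quantized images (<= 64 distinct levels)
  set.seed(101)
  for (i in 1:12) {
    lev <- sort(sample(0:255, sample(3:64, 1))) / 255
    v <- sample(lev, 400, replace = TRUE)
    thr <- otsu_threshold(v)
    expect_equal(between_class_variance(v, thr), otsu_bruteforce(v)$bcv,
                 tolerance = 1e-12)
  }

  # degenerate: single level -> zero infarct, flagged
  flat <- classify_infarct(matrix(0.1, 20, 20), tis)
  expect_true(flagged <- flat$flagged)
  expect_equal(sum(flat$mask), 0)

  # unimodal noise is refused by the contrast guard
  set.seed(7)
  noisy <- matrix(pmin(pmax(round(255 * 0.15 + rnorm(400, 0, 6)), 0), 255) / 255,
                  20, 20)
  guard <- classify_infarct(noisy, tis)
  expect_true(guard$flagged)
  expect_equal(sum(guard$mask), 0)

  # fixed threshold
  gray2 <- matrix(c(rep(0.2, 300), rep(0.7, 100)), 20, 20)
  fx <- classify_infarct(gray2, tis, method = "fixed", level = 0.5)
  expect_equal(sum(fx$mask), 100)
  expect_error(classify_infarct(gray2, tis, method = "fixed"), "level")
})

test_that("blue detection is a dominance rule with a configurable margin", {
  px <- paint_rect(rgb_canvas(64, 64), 13:52, 13:52, c(190, 40, 40))
  px <- paint_rect(px, 20:29, 20:31, c(40, 40, 180))    # 10 x 12 EB zone
  img <- slice_image(px, 1)
  tis <- segment_tissue(img)

  bl <- detect_blue_area(img, tis)
  expect_equal(bl$area_px, 120)

  # white + red tissue has no blue pixels
  bare <- slice_image(paint_rect(rgb_canvas(64, 64), 13:52, 13:52,
                                 c(190, 40, 40)), 1)
  expect_equal(detect_blue_area(bare, segment_tissue(bare))$area_px, 0)

  expect_error(detect_blue_area(img, tis, blue_margin = 1.2), "\\(0, 1\\)")
})

test_that("measure_slice composes the pipeline and attributes areas correctly", {
  # symmetric EB-free phantom slice: no infarct, no blue, equal hemispheres
  p0 <- phantom_params(n_slices = 1, noise_sd = 0)
  g0 <- generate_brain(p0)
  m0 <- measure_slice(g0$images[[1]])
  expect_equal(m0$infarct_area_px, 0)
  expect_equal(m0$blue_area_px, 0)
  expect_equal(m0$left_area_px, m0$right_area_px)
  expect_match(m0$flags, "low_contrast")

  # infarct + EB phantom: painted counts recovered within 3%
  p <- phantom_params(swelling_factor = 1.05, infarct_fraction = 0.2,
                      eb_fraction = 0.5, seed = 11)
  g <- generate_brain(p)
  ms <- do.call(rbind, lapply(g$images, measure_slice))
  expect_equal(ms$infarct_area_px, g$truth$per_slice$infarct_area_px,
               tolerance = 0.03)
  expect_equal(ms$blue_area_px, g$truth$per_slice$blue_area_px,
               tolerance = 0.03)
  # conservation on every slice
  expect_equal(ms$left_area_px + ms$right_area_px,
               g$truth$per_slice$left_area_px +
                 g$truth$per_slice$right_area_px, tolerance = 0.01)
})

test_that("blue filter makes infarct measurement invariant to the EB overlay", {
  base <- list(swelling_factor = 1.05, infarct_fraction = 0.25, seed = 21)
  with_eb <- generate_brain(do.call(phantom_params, c(base, eb_fraction = 0.8)))
  no_eb <- generate_brain(do.call(phantom_params, c(base, eb_fraction = 0)))
  inf_with <- sum(do.call(rbind, lapply(with_eb$images,
                                        measure_slice))$infarct_area_px)
  inf_without <- sum(do.call(rbind, lapply(no_eb$images,
                                           measure_slice))$infarct_area_px)
  expect_lt(abs(inf_with - inf_without) / inf_without, 0.01)

  # the unfiltered luminance pipeline swallows the EB zone into "viable"
  cfg0 <- slice_config(use_blue_filter = FALSE)
  inf_raw <- sum(do.call(rbind, lapply(with_eb$images, measure_slice,
                                       config = cfg0))$infarct_area_px)
  expect_gt((inf_without - inf_raw) / inf_without, 0.25)
})

test_that("blue area grows monotonically with the painted EB extent", {
  areas <- vapply(c(0.2, 0.4, 0.6, 0.8, 1.0), function(eb) {
    g <- generate_brain(phantom_params(n_slices = 1, infarct_fraction = 0.3,
                                       eb_fraction = eb, seed = 31))
    measure_slice(g$images[[1]])$blue_area_px
  }, numeric(1))
  expect_true(all(diff(areas) >= 0))
  expect_gt(areas[5], areas[1])
})
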