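test_that("histogram equalization matches a hand-computed CDF table", {
  # 4 pixels at 4 quantization levels: bins 0..3, each with count 1,
  # CDF = 0.25, 0.5, 0.75, 1.
  img <- matrix(c(0, 1/3, 2/3, 1), 4, 1)
  out <- equalize_hist(img, levels = 4)
  expect_equal(as.vector(out), c(0.25, 0.5, 0.75, 1.0))
})

test_that("equalization fixes uniform histograms and constant images", {
  # already-uniform histogram: one pixel per level
  n <- 256
  img <- matrix((seq_len(n) - 0.5) / n, n, 1)
  out <- equalize_hist(img)
  expect_lt(max(abs(out - img)), 1 / 256 + 1e-12)
  # constant image: degenerate histogram, unchanged
  cimg <- matrix(0.42, 5, 5)
  expect_identical(equalize_hist(cimg), cimg)
  # mapping is monotone in the input gray level
  set.seed(1)
  x <- matrix(runif(400), 20, 20)
  y <- equalize_hist(x)
  expect_true(all(diff(y[order(x)]) >= 0))
})

test_that("equalization is idempotent within quantization tolerance", {
  set.seed(2)
  x <- matrix(runif(1024), 32, 32)
  once <- equalize_hist(x)
  twice <- equalize_hist(once)
  expect_lt(max(abs(twice - once)), 2 / 256)
})

test_that("adaptive equalization degenerates to global HE for one unclipped tile", {
  set.seed(3)
  x <- matrix(runif(1024), 32, 32)
  expect_equal(equalize_adaptive(x, tile_grid = c(1, 1), clip_limit = Inf),
               equalize_hist(x))
  cimg <- matrix(0.3, 16, 16)
  expect_identical(equalize_adaptive(cimg), cimg)
})

test_that("per-tile-constant images are left unchanged by CLAHE, matching per-tile HE", {
  img <- cbind(matrix(0.25, 8, 4), matrix(0.75, 8, 4))
  out <- equalize_adaptive(img, tile_grid = c(1, 2), clip_limit = Inf)
  # per-tile HE of a constant tile is the identity; the blended LUTs of
  # two identity mappings must also be the identity (to half-bin accuracy)
  expect_lt(max(abs(out - img)), 1 / 256)
  left <- equalize_hist(img[, 1:4])
  right <- equalize_hist(img[, 5:8])
  expect_lt(max(abs(out - cbind(left, right))), 1 / 256)
})

test_that("CLAHE increases local contrast and tracks an independent implementation", {
  # low-contrast ramp plus texture: local std must not decrease overall
  set.seed(4)
  base <- outer(seq(0.4, 0.6, length.out = 64), rep(1, 64))
  x <- pmin(pmax(base + matrix(rnorm(64 * 64, 0, 0.01), 64, 64), 0), 1)
  y <- equalize_adaptive(x, tile_grid = c(4, 4), clip_limit = 4)
  expect_gt(sd(y), sd(x))
  # independent cross-check: EBImage's CLAHE on the same input
  z <- as.matrix(EBImage::clahe(x, nx = 4, ny = 4, limit = 4))
  expect_gt(cor(as.vector(y), as.vector(z)), 0.9)
})

test_that("CLAHE with oversized tiles falls back to global HE with a warning", {
  set.seed(5)
  x <- matrix(runif(64), 8, 8)
  expect_warning(out <- equalize_adaptive(x, tile_grid = c(16, 16)),
                 "global HE")
  expect_equal(out, equalize_hist(x))
})

test_that("min-max normalization rescales, is idempotent, and handles constants", {
  expect_equal(as.vector(normalize_image(matrix(c(2, 4, 6), 1, 3))),
               c(0, 0.5, 1))
  x <- matrix(c(0, 0.3, 0.7, 1), 2, 2)
  expect_identical(normalize_image(x), x)
  expect_equal(normalize_image(matrix(5, 3, 3)), matrix(0.5, 3, 3))
})

test_that("random crop applies one shared window and restores size", {
  set.seed(6)
  img <- matrix(runif(64 * 64), 64, 64)
  mask <- matrix(0L, 64, 64); mask[30, 33] <- 1L
  cfg <- augment_config(crop_fraction = 1)
  p <- random_crop(img, mask, cfg)
  expect_equal(p$image, img)
  expect_identical(p$mask, mask)
  # window coordinates equal the directly drawn integers
  cfg <- augment_config(crop_fraction = 0.5)
  set.seed(7)
  p <- random_crop(img, mask, cfg)
  set.seed(7)
  expect_equal(p$meta$top, sample.int(64 - 32 + 1, 1))
  expect_equal(p$meta$left, sample.int(64 - 32 + 1, 1))
  # a window that covers the single foreground pixel keeps count 1 pre-resize
  found <- FALSE
  for (s in 1:50) {
    set.seed(s)
    p <- random_crop(img, mask, cfg)
    w <- p$meta
    if (30 >= w$top && 30 < w$top + w$h && 33 >= w$left && 33 < w$left + w$w) {
      cropped <- mask[w$top:(w$top + w$h - 1), w$left:(w$left + w$w - 1)]
      expect_equal(sum(cropped), 1L)
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("flips reverse indices exactly and are involutions", {
  img <- matrix(1:4 / 4, 2, 2)       # asymmetric 2x2 pattern
  mask <- matrix(c(0L, 1L, 2L, 0L), 2, 2)
  h <- flip_pair(img, mask, "horizontal")
  expect_equal(h$image, img[, 2:1])
  expect_identical(h$mask, mask[, 2:1])
  v <- flip_pair(h$image, h$mask, "horizontal")
  expect_equal(v$image, img)
  expect_identical(v$mask, mask)
  vv <- flip_pair(flip_pair(img, mask, "vertical")$image,
                  flip_pair(img, mask, "vertical")$mask, "vertical")
  expect_equal(vv$image, img)
  # left-right symmetric image unchanged
  s <- matrix(c(1, 1, 2, 2), 2, 2, byrow = TRUE) / 2
  expect_equal(flip_pair(s, mask, "horizontal")$image, s)
})

test_that("gray perturbation is additive Gaussian with the configured scale", {
  img <- matrix(0.5, 1000, 1000)
  cfg <- augment_config(gray_sigma = 0.01)   # far from clipping at 0.5
  expect_identical(gray_perturb(img, augment_config(gray_sigma = 0)), img)
  set.seed(8)
  a <- gray_perturb(img, cfg)
  set.seed(8)
  b <- gray_perturb(img, cfg)
  expect_identical(a, b)
  # Monte-Carlo estimate of the noise scale over 1e6 pixels
  expect_equal(sd(a - img), 0.01, tolerance = 0.01)
  expect_equal(mean(a - img), 0, tolerance = 1e-4)
})

test_that("shape perturbation with zero jitter is the bit-exact identity", {
  set.seed(9)
  img <- matrix(runif(32 * 32), 32, 32)
  mask <- matrix(sample(0:2, 32 * 32, TRUE), 32, 32)
  p <- shape_perturb(img, mask, augment_config(vertex_shift_fraction = 0))
  expect_identical(p$image, img)
  expect_identical(p$mask, mask)
})

test_that("the affine map is recovered exactly from the three vertex correspondences", {
  set.seed(10)
  src <- rbind(c(1, 1), c(1, 32), c(32, 1))
  for (rep in 1:10) {
    dst <- src + matrix(runif(6, -3, 3), 3, 2)
    m <- toothseg:::affine_from_triangle(src, dst)
    expect_equal(cbind(src, 1) %*% m, dst, tolerance = 1e-10)
  }
})

test_that("pure translation jitter shifts content like direct index shifting", {
  set.seed(11)
  img <- matrix(runif(24 * 24), 24, 24)
  src <- rbind(c(1, 1), c(1, 24), c(24, 1))
  dst <- src + matrix(rep(c(3, 2), each = 3), 3, 2)   # rows +3, cols +2
  m <- toothseg:::affine_from_triangle(src, dst)
  out <- as.matrix(EBImage::affine(img, m, filter = "none", bg.col = 0))
  shifted <- matrix(0, 24, 24)
  shifted[4:24, 3:24] <- img[1:21, 1:22]
  expect_equal(out, shifted)
})

test_that("augmentation never invents mask classes", {
  set.seed(12)
  cfg <- augment_config(seed = 3)
  sp <- generate_slice(phantom_config(image_size = 64, instance_labels = TRUE,
                                      n_teeth = 4L, seed = 21))
  for (rep in 1:5) {
    p <- toothseg:::augment_once(sp, cfg)
    expect_true(all(unique(as.integer(p$mask)) %in%
                    c(0L, unique(as.integer(sp$mask)))))
    expect_identical(dim(p$image), dim(sp$image))
  }
})

test_that("dataset enlargement yields factor-times-n samples, original included", {
  sp <- generate_slice(phantom_config(image_size = 32, seed = 31))
  pairs <- replicate(10, sp, simplify = FALSE)
  out4 <- enlarge_dataset(pairs, augment_config(enlargement_factor = 4,
                                                seed = 5))
  expect_length(out4, 40)
  expect_identical(out4[[1]]$image, sp$image)
  out1 <- enlarge_dataset(pairs, augment_config(enlargement_factor = 1))
  expect_identical(out1, pairs)
  expect_length(enlarge_dataset(list(), augment_config()), 0)
  # deterministic in the configured seed
  a <- enlarge_dataset(pairs[1:2], augment_config(enlargement_factor = 3,
                                                  seed = 9))
  b <- enlarge_dataset(pairs[1:2], augment_config(enlargement_factor = 3,
                                                  seed = 9))
  expect_identical(a, b)
})
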