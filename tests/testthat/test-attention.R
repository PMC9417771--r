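test_that("global average pooling squeezes channels to their spatial means", {
  u <- array(c(1, 3, 2, 4), c(2, 2, 1))   # [[1,2],[3,4]] column-major
  expect_equal(as.numeric(gap_squeeze(u)), 2.5)
  v <- array(0.7, c(3, 5, 4))
  expect_equal(as.numeric(gap_squeeze(v)), rep(0.7, 4))
  set.seed(1)
  w <- rand_map(5, 7, 3)
  expect_equal(as.numeric(gap_squeeze(w)), oracle_gap(w), tolerance = 1e-12)
})

test_that("excitation gates through the bottleneck into (0,1)", {
  p0 <- se_params(4, C = 2, W1 = matrix(0, 2, 4), W2 = matrix(0, 4, 2))
  expect_equal(as.numeric(excite(c(1, -2, 3, 0.5), p0)), rep(0.5, 4))
  set.seed(2)
  p <- se_params(8, C = 2)
  s <- excite(rnorm(8), p)
  expect_true(all(s > 0 & s < 1))
  expect_identical(attr(s, "range_tag"), "sigmoid")
  # hand-set weights against the explicit matrix-vector chain
  W1 <- matrix(c(0.5, -1, 0.25, 2, 1, 0, -0.5, 0.75), 2, 4)
  W2 <- matrix(seq(-0.8, 0.6, length.out = 8), 4, 2)
  ph <- se_params(4, C = 2, W1 = W1, W2 = W2)
  z <- c(0.2, -0.4, 1.1, 0.9)
  expect_equal(as.numeric(excite(z, ph)), oracle_excite(z, W1, W2),
               tolerance = 1e-12)
  expect_error(excite(rnorm(3), ph), "match K")
})

test_that("non-divisible channel counts round the bottleneck up with a note", {
  expect_message(p <- se_params(6, C = 4), "rounded up")
  expect_equal(nrow(p$W1), 2)
})

test_that("channel rescaling multiplies each channel by its weight", {
  set.seed(3)
  u <- rand_map(4, 5, 3)
  expect_equal(rescale(u, c(1, 1, 1)), u)
  expect_equal(rescale(u, c(0, 0, 0)), array(0, dim(u)))
  s <- runif(3, 0.2, 1.8)
  expect_equal(rescale(u, s), oracle_rescale(u, s), tolerance = 1e-12)
  expect_error(rescale(u, c(1, 2)), "channel count")
})

test_that("sub-region pooling averages grid cells and degenerates correctly", {
  set.seed(4)
  u <- rand_map(4, 4, 2)
  # grid (2,2): four quadrant means per channel
  expect_equal(sap_pool(u, c(2, 2)), oracle_sap_pool(u, c(2, 2)),
               tolerance = 1e-12)
  # grid (1,1) reduces to GAP
  expect_equal(as.numeric(sap_pool(u, c(1, 1))), as.numeric(gap_squeeze(u)),
               tolerance = 1e-14)
  # grid (H,W) is the identity
  expect_equal(sap_pool(u, c(4, 4)), u)
  expect_error(sap_pool(u, c(5, 2)), "exceeds spatial size")
})

test_that("cell means average back to the GAP value on evenly divisible grids", {
  set.seed(5)
  for (rep in 1:20) {
    m <- sample(1:4, 1); n <- sample(1:4, 1)
    u <- rand_map(m * sample(1:5, 1), n * sample(1:5, 1), sample(1:4, 1))
    pooled <- sap_pool(u, c(m, n))
    expect_equal(apply(pooled, 3, mean), as.numeric(gap_squeeze(u)),
                 tolerance = 1e-12)
  }
})

test_that("SAP attention applies the per-channel grid kernel summed over inputs", {
  set.seed(6)
  u <- rand_map(6, 8, 3)
  # zero kernels: sigmoid(0) = 0.5 everywhere
  p0 <- sap_params(c(2, 2), K = 3, conv_kernel = array(0, c(2, 2, 3)))
  expect_equal(as.numeric(sap_attention(u, p0)), rep(0.5, 3))
  # grid (1,1), unit kernel on channel r only: reduces to GAP + sigmoid
  # of the summed channel means
  k1 <- array(1, c(1, 1, 3))
  p1 <- sap_params(c(1, 1), K = 3, conv_kernel = k1)
  expect_equal(as.numeric(sap_attention(u, p1)),
               rep(1 / (1 + exp(-sum(gap_squeeze(u)))), 3),
               tolerance = 1e-12)
  # random kernels against the brute-force summation oracle
  set.seed(7)
  for (rep in 1:10) {
    p <- sap_params(c(2, 3), K = 4)
    v <- rand_map(7, 9, 4)
    expect_equal(as.numeric(sap_attention(v, p)),
                 oracle_sap_attention(v, p$conv_kernel, c(2, 3)),
                 tolerance = 1e-10)
  }
})

test_that("CE attention expands low-level channels to the high-level count", {
  set.seed(8)
  low <- rand_map(8, 8, 3)
  pz <- sap_params(c(2, 2), K = 5, K_low = 3,
                   ce_weights = matrix(0, 5, 3))
  expect_equal(as.numeric(ce_attention(low, pz)), rep(0.5, 5))
  # identity expansion with grid (1,1): sigmoid of per-channel means
  pid <- sap_params(c(1, 1), K = 3, K_low = 3, ce_weights = diag(3))
  expect_equal(as.numeric(ce_attention(low, pid)),
               1 / (1 + exp(-as.numeric(gap_squeeze(low)))),
               tolerance = 1e-12)
  # random case against the matrix-product oracle
  p <- sap_params(c(2, 2), K = 6, K_low = 3)
  v <- apply(oracle_sap_pool(low, c(2, 2)), 3, mean)
  expect_equal(as.numeric(ce_attention(low, p)),
               1 / (1 + exp(-as.vector(p$ce_weights %*% v))),
               tolerance = 1e-12)
  expect_error(ce_attention(rand_map(4, 4, 2), p), "channel count")
})

test_that("fused attention weights sum elementwise and stay in (0,2)", {
  l <- channel_weights(c(0.5, 0.5), "sigmoid")
  h <- channel_weights(c(0.5, 0.5), "sigmoid")
  expect_equal(as.numeric(fuse_attention(l, h)), c(1, 1))
  a <- channel_weights(c(0.1, 0.9), "sigmoid")
  b <- channel_weights(c(0.2, 0.3), "sigmoid")
  f <- fuse_attention(a, b)
  expect_equal(as.numeric(f), c(0.3, 1.2))
  expect_identical(attr(f, "range_tag"), "fused")
  set.seed(9)
  for (rep in 1:50) {
    x <- channel_weights(1 / (1 + exp(-rnorm(8, 0, 5))), "sigmoid")
    y <- channel_weights(1 / (1 + exp(-rnorm(8, 0, 5))), "sigmoid")
    z <- fuse_attention(x, y)
    expect_true(all(z > 0 & z < 2))
  }
  # double fusion and raw inputs are rejected
  expect_error(fuse_attention(f, b), "sigmoid-tagged")
  expect_error(fuse_attention(channel_weights(c(1, 2), "raw"), b),
               "sigmoid-tagged")
  expect_error(fuse_attention(a, channel_weights(0.5, "sigmoid")), "length")
})

test_that("recalibration scales channels by the fused weights", {
  set.seed(10)
  U <- rand_map(5, 6, 3)
  ones <- channel_weights(rep(1, 3), "fused")
  expect_equal(recalibrate(U, ones), U)
  w <- channel_weights(c(0.4, 1.5, 1.0), "fused")
  expect_equal(recalibrate(U, w), oracle_rescale(U, c(0.4, 1.5, 1.0)),
               tolerance = 1e-12)
  # amplification: the 1.5 channel exceeds its input magnitude
  expect_equal(max(abs(recalibrate(U, w)[, , 2])), 1.5 * max(abs(U[, , 2])))
  # weights near zero shrink the map toward zero
  tiny <- channel_weights(rep(1e-9, 3), "fused")
  expect_lt(max(abs(recalibrate(U, tiny))), 1e-8)
  expect_error(recalibrate(U, channel_weights(rep(0.5, 3), "sigmoid")),
               "fused")
})

test_that("the attended pipeline preserves feature-map shape", {
  set.seed(11)
  u <- rand_map(8, 12, 6)
  low <- rand_map(8, 12, 4)
  p <- sap_params(c(2, 2), K = 6, K_low = 4)
  eh <- sap_attention(u, p)
  el <- ce_attention(low, p)
  out <- recalibrate(u, fuse_attention(el, eh))
  expect_identical(dim(out), dim(u))
})

test_that("channel weight tags enforce their ranges", {
  expect_error(channel_weights(c(0.5, 1.0), "sigmoid"), "strictly")
  expect_error(channel_weights(c(2.0), "fused"), "strictly")
  expect_silent(channel_weights(c(1.999, 0.001), "fused"))
})
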