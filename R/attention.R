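#' Channel-attention blocks
#'
#' The attention mechanism works on H x W x K feature maps and produces a
#' length-K vector of channel weights. The squeeze-excite baseline pools
#' each channel to its global mean (GAP), passes the K-vector through a
#' two-layer bottleneck with reduction ratio C, and gates channels with a
#' sigmoid. The sub-region average pooling (SAP) variant keeps an m x n
#' grid of spatial means per channel before the attention convolution, so
#' coarse spatial layout still informs the channel weights. A
#' channel-expansion (CE) branch produces analogous weights from a
#' low-level (skip) feature and aligns them with the high-level channel
#' count; the two sigmoid-bounded distributions are fused by elementwise
#' addition, giving weights in (0,2) that can attenuate or amplify each
#' channel during recalibration.
#'
#' @name attention
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Tagged channel-weight vector
#'
#' @param w Numeric vector, one weight per channel.
#' @param range_tag `"raw"` (unbounded pooled values), `"sigmoid"`
#'   (components strictly in (0,1)), or `"fused"` (components strictly in
#'   (0,2), the sum of two sigmoid-bounded vectors).
#' @return Numeric vector with a `range_tag` attribute and class
#'   `channel_weights`.
#' @export
channel_weights <- function(w, range_tag = c("raw", "sigmoid", "fused")) {
  range_tag <- match.arg(range_tag)
  if (range_tag == "sigmoid" && (any(w <= 0) || any(w >= 1)))
    stop("sigmoid-tagged weights must lie strictly in (0,1)", call. = FALSE)
  if (range_tag == "fused" && (any(w <= 0) || any(w >= 2)))
    stop("fused weights must lie strictly in (0,2)", call. = FALSE)
  structure(as.numeric(w), range_tag = range_tag, class = "channel_weights")
}

weight_tag <- function(w) attr(w, "range_tag")

#' Global average pooling squeeze
#'
#' Shrinks an H x W x K feature map to the length-K vector of per-channel
#' spatial means.
#'
#' @param u Numeric H x W x K array.
#' @return Raw-tagged [channel_weights()] of length K.
#' @export
gap_squeeze <- function(u) {
  stopifnot(is.array(u), length(dim(u)) == 3L)
  channel_weights(apply(u, 3, mean), "raw")
}

#' Squeeze-excite bottleneck parameters
#'
#' Holds the two fully connected transforms of the excitation: `W1`
#' ((K/C) x K) reduces the pooled vector, `W2` (K x (K/C)) restores it to
#' K dimensions before the sigmoid gate. When K is not divisible by the
#' reduction ratio C, the bottleneck width is rounded up (with a message).
#'
#' @param K Channel count.
#' @param C Reduction ratio (default 16).
#' @param W1,W2 Optional explicit weight matrices; random
#'   He-scaled draws when omitted.
#' @return An object of class `se_params`.
#' @export
se_params <- function(K, C = 16L, W1 = NULL, W2 = NULL) {
  stopifnot(K >= 1, C >= 1)
  Kb <- K / C
  if (Kb != round(Kb)) {
    Kb <- ceiling(Kb)
    message("K = ", K, " not divisible by C = ", C,
            "; bottleneck width rounded up to ", Kb)
  }
  Kb <- max(1L, as.integer(Kb))
  if (is.null(W1)) W1 <- matrix(stats::rnorm(Kb * K, 0, sqrt(2 / K)), Kb, K)
  if (is.null(W2)) W2 <- matrix(stats::rnorm(K * Kb, 0, sqrt(2 / Kb)), K, Kb)
  stopifnot(nrow(W1) == Kb, ncol(W1) == K, nrow(W2) == K, ncol(W2) == Kb)
  structure(list(W1 = W1, W2 = W2, K = as.integer(K), C = as.integer(C)),
            class = "se_params")
}

#' Excitation: bottleneck transform and sigmoid gate
#'
#' `s = sigmoid(W2 . relu(W1 . z))`; every component lies strictly in
#' (0,1).
#'
#' @param z Length-K pooled channel vector (e.g. from [gap_squeeze()]).
#' @param p An [se_params()].
#' @return Sigmoid-tagged [channel_weights()] of length K.
#' @export
excite <- function(z, p) {
  stopifnot(inherits(p, "se_params"))
  if (length(z) != p$K)
    stop("length of z (", length(z), ") does not match K (", p$K, ")",
         call. = FALSE)
  h <- pmax(as.vector(p$W1 %*% as.numeric(z)), 0)
  channel_weights(sigmoid(as.vector(p$W2 %*% h)), "sigmoid")
}

#' Channel-wise rescaling (the scale operation)
#'
#' Multiplies channel c of the feature map by weight s_c; spatial size and
#' channel count are unchanged.
#'
#' @param u Numeric H x W x K array.
#' @param s Channel weights of length K.
#' @return H x W x K array.
#' @export
rescale <- function(u, s) {
  stopifnot(is.array(u), length(dim(u)) == 3L)
  if (dim(u)[3] != length(s))
    stop("channel count ", dim(u)[3], " does not match weight length ",
         length(s), call. = FALSE)
  sweep(u, 3, as.numeric(s), `*`)
}

#' Sub-region average pooling
#'
#' Partitions the spatial plane into an m x n grid of near-equal
#' rectangles (boundaries at `floor(H*i/m)`, `floor(W*j/n)`) and replaces
#' each cell by its mean, per channel: an H x W x K map becomes m x n x K.
#' Grid (1,1) reduces to global average pooling; grid (H,W) is the
#' identity.
#'
#' @param u Numeric H x W x K array.
#' @param grid Integer vector `c(m, n)`, with m <= H and n <= W.
#' @return m x n x K array of cell means.
#' @export
sap_pool <- function(u, grid) {
  stopifnot(is.array(u), length(dim(u)) == 3L)
  H <- dim(u)[1]; W <- dim(u)[2]; K <- dim(u)[3]
  m <- grid[1]; n <- grid[2]
  if (m > H || n > W)
    stop("pooling grid (", m, ",", n, ") exceeds spatial size (",
         H, ",", W, ")", call. = FALSE)
  rb <- floor(H * (0:m) / m)
  cb <- floor(W * (0:n) / n)
  out <- array(0, c(m, n, K))
  for (i in seq_len(m)) for (j in seq_len(n)) {
    out[i, j, ] <- apply(u[(rb[i] + 1):rb[i + 1], (cb[j] + 1):cb[j + 1], ,
                           drop = FALSE], 3, mean)
  }
  out
}

#' SAP attention parameters
#'
#' @param grid Sub-region grid `c(m, n)`.
#' @param K High-level channel count (one m x n kernel per output
#'   channel).
#' @param K_low Low-level channel count seen by the CE branch (defaults to
#'   K).
#' @param conv_kernel Optional explicit m x n x K kernel array.
#' @param ce_weights Optional explicit K x K_low channel-expansion matrix.
#' @return An object of class `sap_params`.
#' @export
sap_params <- function(grid, K, K_low = K, conv_kernel = NULL,
                       ce_weights = NULL) {
  m <- as.integer(grid[1]); n <- as.integer(grid[2])
  stopifnot(m >= 1, n >= 1, K >= 1, K_low >= 1)
  if (is.null(conv_kernel))
    conv_kernel <- array(stats::rnorm(m * n * K, 0, sqrt(2 / (m * n * K))),
                         c(m, n, K))
  if (is.null(ce_weights))
    ce_weights <- matrix(stats::rnorm(K * K_low, 0, sqrt(2 / K_low)),
                         K, K_low)
  stopifnot(all(dim(conv_kernel) == c(m, n, K)),
            nrow(ce_weights) == K, ncol(ce_weights) == K_low)
  structure(list(grid = c(m, n), conv_kernel = conv_kernel,
                 ce_weights = ce_weights, K = as.integer(K),
                 K_low = as.integer(K_low)),
            class = "sap_params")
}

#' High-level channel attention from sub-region pooling
#'
#' Pools `u` to the m x n grid, then for each output channel r applies the
#' m x n kernel phi_r across the grid and sums over all input channels; a
#' sigmoid of the resulting scalar gives the attention weight:
#' `eps_r = sigmoid( sum_i sum_{a,b} phi_r[a,b] * Fhat[a,b,i] )`.
#'
#' @param u Numeric H x W x K array.
#' @param p A [sap_params()] with `K == dim(u)[3]`.
#' @return Sigmoid-tagged [channel_weights()] of length K (the high-level
#'   distribution eps_h).
#' @export
sap_attention <- function(u, p) {
  stopifnot(inherits(p, "sap_params"))
  if (dim(u)[3] != p$K)
    stop("channel count mismatch: feature has ", dim(u)[3],
         " channels, kernel expects ", p$K, call. = FALSE)
  fhat <- sap_pool(u, p$grid)
  cell_sums <- apply(fhat, c(1, 2), sum)          # sum over input channels
  pre <- apply(p$conv_kernel, 3, function(phi) sum(phi * cell_sums))
  channel_weights(sigmoid(pre), "sigmoid")
}

#' Low-level channel attention through channel expansion
#'
#' Pools the low-level feature to the sub-region grid, averages the grid
#' cells per channel, and maps the resulting K_low vector to the
#' high-level channel count with the 1 x 1 channel-expansion weights
#' before the sigmoid: `eps_l = sigmoid(W_ce . mean_cells(sap_pool(low)))`.
#'
#' @param low Numeric H x W x K_low array (the skip feature).
#' @param p A [sap_params()] with `K_low == dim(low)[3]`.
#' @return Sigmoid-tagged [channel_weights()] of length K (the low-level
#'   distribution eps_l, aligned with the high-level channels).
#' @export
ce_attention <- function(low, p) {
  stopifnot(inherits(p, "sap_params"))
  if (dim(low)[3] != p$K_low)
    stop("channel count mismatch: low-level feature has ", dim(low)[3],
         " channels, CE weights expect ", p$K_low, call. = FALSE)
  grid <- pmin(p$grid, dim(low)[1:2])
  pooled <- sap_pool(low, grid)
  v <- apply(pooled, 3, mean)
  channel_weights(sigmoid(as.vector(p$ce_weights %*% v)), "sigmoid")
}

#' Fuse low- and high-level attention distributions
#'
#' Elementwise sum of the two sigmoid-bounded vectors. Each fused
#' component lies strictly in (0,2) — the weight can attenuate (< 1) or
#' amplify (> 1) a channel. Fusing an already-fused vector is rejected.
#'
#' @param eps_l,eps_h Sigmoid-tagged [channel_weights()] of equal length.
#' @return Fused-tagged [channel_weights()].
#' @export
fuse_attention <- function(eps_l, eps_h) {
  if (!identical(weight_tag(eps_l), "sigmoid") ||
      !identical(weight_tag(eps_h), "sigmoid"))
    stop("fuse_attention needs two sigmoid-tagged inputs (double fusion ",
         "or raw pooled values are not allowed)", call. = FALSE)
  if (length(eps_l) != length(eps_h))
    stop("attention vectors differ in length", call. = FALSE)
  channel_weights(as.numeric(eps_l) + as.numeric(eps_h), "fused")
}

#' Recalibrate a feature map with fused attention weights
#'
#' Channel-wise product of the feature map with the fused weights; because
#' the weights range over (0,2), a channel's values can be amplified as
#' well as suppressed.
#'
#' @param U Numeric H x W x K array.
#' @param eps_F Fused-tagged [channel_weights()] of length K.
#' @return H x W x K array, same shape as `U`.
#' @export
recalibrate <- function(U, eps_F) {
  if (!identical(weight_tag(eps_F), "fused"))
    stop("recalibrate expects fused-tagged weights", call. = FALSE)
  rescale(U, eps_F)
}
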