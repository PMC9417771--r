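# Independent brute-force oracles used by unit and acceptance tests.
# These deliberately use naive loops / explicit pixel sets, not the
# package's own vectorized code paths.

# Per-channel mean by explicit double loop.
oracle_gap <- function(u) {
  K <- dim(u)[3]
  out <- numeric(K)
  for (c in seq_len(K)) {
    s <- 0
    for (i in seq_len(dim(u)[1])) for (j in seq_len(dim(u)[2]))
      s <- s + u[i, j, c]
    out[c] <- s / (dim(u)[1] * dim(u)[2])
  }
  out
}

# Elementwise channel product by triple loop.
oracle_rescale <- function(u, s) {
  out <- array(0, dim(u))
  for (i in seq_len(dim(u)[1])) for (j in seq_len(dim(u)[2]))
    for (c in seq_len(dim(u)[3]))
      out[i, j, c] <- u[i, j, c] * s[c]
  out
}

# Sub-region average pooling by explicit per-cell loops (same near-equal
# partition boundaries as the implementation contract: floor(H*i/m)).
oracle_sap_pool <- function(u, grid) {
  H <- dim(u)[1]; W <- dim(u)[2]; K <- dim(u)[3]
  m <- grid[1]; n <- grid[2]
  out <- array(0, c(m, n, K))
  for (i in seq_len(m)) for (j in seq_len(n)) for (c in seq_len(K)) {
    rows <- (floor(H * (i - 1) / m) + 1):floor(H * i / m)
    cols <- (floor(W * (j - 1) / n) + 1):floor(W * j / n)
    s <- 0
    for (r in rows) for (cc in cols) s <- s + u[r, cc, c]
    out[i, j, c] <- s / (length(rows) * length(cols))
  }
  out
}

# SAP attention pre-activations by explicit sum over grid cells and
# input channels.
oracle_sap_attention <- function(u, phi, grid) {
  fhat <- oracle_sap_pool(u, grid)
  K <- dim(phi)[3]
  pre <- numeric(K)
  for (r in seq_len(K)) {
    s <- 0
    for (a in seq_len(grid[1])) for (b in seq_len(grid[2]))
      for (i in seq_len(dim(fhat)[3]))
        s <- s + phi[a, b, r] * fhat[a, b, i]
    pre[r] <- s
  }
  1 / (1 + exp(-pre))
}

# Squeeze-excite chain by explicit matrix-vector arithmetic.
oracle_excite <- function(z, W1, W2) {
  h <- as.vector(W1 %*% z)
  h[h < 0] <- 0
  1 / (1 + exp(-as.vector(W2 %*% h)))
}

# Set-based per-class accuracy / IoU directly from pixel label sets,
# with undefined (empty) classes dropped from the averages.
oracle_metrics <- function(truth, pred, k) {
  pa <- iou <- rep(NA_real_, k + 1)
  for (c in 0:k) {
    in_t <- truth == c
    in_p <- pred == c
    inter <- sum(in_t & in_p)
    uni <- sum(in_t | in_p)
    if (sum(in_t) > 0) pa[c + 1] <- inter / sum(in_t)
    if (uni > 0) iou[c + 1] <- inter / uni
  }
  list(mpa = mean(pa, na.rm = TRUE), miou = mean(iou, na.rm = TRUE))
}

# Confusion matrix by per-pixel double loop.
oracle_confusion <- function(truth, pred, k) {
  m <- matrix(0, k + 1, k + 1)
  for (i in seq_len(nrow(truth))) for (j in seq_len(ncol(truth)))
    m[truth[i, j] + 1, pred[i, j] + 1] <- m[truth[i, j] + 1, pred[i, j] + 1] + 1
  m
}

# Brute-force rasterization of a rotated ellipse by per-pixel test.
oracle_ellipse_count <- function(size, cy, cx, a, b, theta) {
  n <- 0
  for (i in seq_len(size)) for (j in seq_len(size)) {
    u <- (i - cy) * cos(theta) + (j - cx) * sin(theta)
    v <- -(i - cy) * sin(theta) + (j - cx) * cos(theta)
    if ((u / a)^2 + (v / b)^2 <= 1) n <- n + 1
  }
  n
}

# Bhattacharyya distance between two gray-level samples on shared bins.
bhattacharyya <- function(x, y, bins = 32) {
  br <- seq(0, 1, length.out = bins + 1)
  p <- hist(x, breaks = br, plot = FALSE)$counts
  q <- hist(y, breaks = br, plot = FALSE)$counts
  p <- p / sum(p); q <- q / sum(q)
  -log(sum(sqrt(p * q)))
}

# Small random feature map.
rand_map <- function(H, W, K) array(stats::rnorm(H * W * K), c(H, W, K))
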