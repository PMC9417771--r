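#' Network layer primitives
#'
#' Minimal CNN building blocks operating on H x W x C numeric arrays, each
#' with an explicit forward pass (returning the output plus a cache) and a
#' matching backward pass (returning input gradients and parameter
#' gradients). Convolution is computed as a sum of per-offset BLAS matrix
#' products: for each kernel tap (a,b) the padded input is shifted,
#' flattened to a (H*W) x C_in matrix, and multiplied by the C_in x C_out
#' slice of the kernel. Up/down-sampling is expressed through 1-D bilinear
#' interpolation matrices so its backward pass is just the transpose.
#'
#' @name nn-primitives
#' @keywords internal
NULL

# He-normal initialization for a kh x kw x Cin x Cout kernel.
conv_init <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

# Zero-pad an H x W x C array by p pixels on each spatial side.
pad_array <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), ] <- x
  out
}

#' Same-padding 2D convolution (stride 1, optional dilation)
#'
#' @param x H x W x Cin array.
#' @param W kh x kw x Cin x Cout kernel (odd kh, kw).
#' @param b Length-Cout bias.
#' @param dilation Integer dilation (expansion) rate.
#' @return List with `out` (H x W x Cout) and a cache for the backward
#'   pass.
#' @keywords internal
conv2d_forward <- function(x, W, b, dilation = 1L) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; cin <- d[3]
  kd <- dim(W); kh <- kd[1]; kw <- kd[2]; cout <- kd[4]
  stopifnot(kd[3] == cin, kh %% 2 == 1, kw %% 2 == 1)
  p <- (kh - 1L) %/% 2L * dilation
  xp <- pad_array(x, p)
  np <- H * Wd
  out <- matrix(rep(b, each = np), np, cout)
  for (ki in seq_len(kh)) for (kj in seq_len(kw)) {
    ro <- (ki - 1L) * dilation
    co <- (kj - 1L) * dilation
    sub <- xp[(1 + ro):(H + ro), (1 + co):(Wd + co), , drop = FALSE]
    dim(sub) <- c(np, cin)
    out <- out + sub %*% matrix(W[ki, kj, , ], cin, cout)
  }
  list(out = array(out, c(H, Wd, cout)),
       cache = list(xp = xp, W = W, dilation = dilation,
                    H = H, Wd = Wd, cin = cin, pad = p))
}

#' @keywords internal
conv2d_backward <- function(dy, cache) {
  W <- cache$W; kd <- dim(W); kh <- kd[1]; kw <- kd[2]; cout <- kd[4]
  H <- cache$H; Wd <- cache$Wd; cin <- cache$cin
  dil <- cache$dilation; p <- cache$pad
  np <- H * Wd
  dy_mat <- dy; dim(dy_mat) <- c(np, cout)
  dW <- array(0, kd)
  dxp <- array(0, dim(cache$xp))
  db <- colSums(dy_mat)
  for (ki in seq_len(kh)) for (kj in seq_len(kw)) {
    ro <- (ki - 1L) * dil
    co <- (kj - 1L) * dil
    sub <- cache$xp[(1 + ro):(H + ro), (1 + co):(Wd + co), , drop = FALSE]
    dim(sub) <- c(np, cin)
    dW[ki, kj, , ] <- crossprod(sub, dy_mat)
    dsub <- dy_mat %*% t(matrix(W[ki, kj, , ], cin, cout))
    dxp[(1 + ro):(H + ro), (1 + co):(Wd + co), ] <-
      dxp[(1 + ro):(H + ro), (1 + co):(Wd + co), , drop = FALSE] +
      array(dsub, c(H, Wd, cin))
  }
  dx <- if (p > 0) dxp[(p + 1):(p + H), (p + 1):(p + Wd), , drop = FALSE]
        else dxp
  list(dx = dx, dW = dW, db = db)
}

#' @keywords internal
relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)

#' @keywords internal
relu_backward <- function(dy, cache) dy * cache

#' 2x2 max pooling (stride 2); spatial dims must be even
#' @keywords internal
maxpool2_forward <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  stopifnot(H %% 2 == 0, W %% 2 == 0)
  ri <- seq(1L, H, 2L); ci <- seq(1L, W, 2L)
  cand <- array(0, c(H / 2, W / 2, C, 4))
  cand[, , , 1] <- x[ri, ci, , drop = FALSE]
  cand[, , , 2] <- x[ri + 1L, ci, , drop = FALSE]
  cand[, , , 3] <- x[ri, ci + 1L, , drop = FALSE]
  cand[, , , 4] <- x[ri + 1L, ci + 1L, , drop = FALSE]
  # deterministic tie-break: first candidate in the fixed order above
  out <- cand[, , , 1]
  which_max <- array(1L, c(H / 2, W / 2, C))
  for (k in 2:4) {
    better <- cand[, , , k] > out
    out[better] <- cand[, , , k][better]
    which_max[better] <- k
  }
  list(out = out, cache = list(which_max = which_max, H = H, W = W, C = C))
}

#' @keywords internal
maxpool2_backward <- function(dy, cache) {
  H <- cache$H; W <- cache$W; C <- cache$C
  wm <- cache$which_max
  dx <- array(0, c(H, W, C))
  ri <- seq(1L, H, 2L); ci <- seq(1L, W, 2L)
  for (k in 1:4) {
    sel <- wm == k
    if (!any(sel)) next
    g <- array(0, dim(dy)); g[sel] <- dy[sel]
    roff <- if (k %in% c(2, 4)) 1L else 0L
    coff <- if (k %in% c(3, 4)) 1L else 0L
    dx[ri + roff, ci + coff, ] <- dx[ri + roff, ci + coff, , drop = FALSE] + g
  }
  dx
}

# 1-D bilinear interpolation matrix mapping length n_in to n_out
# (half-pixel center alignment, edges clamped).
bilinear_matrix <- function(n_out, n_in) {
  if (n_out == n_in) return(diag(n_in))
  src <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  src <- pmin(pmax(src, 1), n_in)
  lo <- pmin(floor(src), n_in - 1L)
  w <- src - lo
  M <- matrix(0, n_out, n_in)
  M[cbind(seq_len(n_out), lo)] <- 1 - w
  M[cbind(seq_len(n_out), lo + 1L)] <- M[cbind(seq_len(n_out), lo + 1L)] + w
  M
}

#' Bilinear resampling of an H x W x C array to (h_out, w_out)
#' @keywords internal
upsample_forward <- function(x, h_out, w_out) {
  d <- dim(x)
  Mh <- bilinear_matrix(h_out, d[1])
  Mw <- bilinear_matrix(w_out, d[2])
  out <- array(0, c(h_out, w_out, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- Mh %*% x[, , c] %*% t(Mw)
  list(out = out, cache = list(Mh = Mh, Mw = Mw, C = d[3]))
}

#' @keywords internal
upsample_backward <- function(dy, cache) {
  h_in <- ncol(cache$Mh); w_in <- ncol(cache$Mw)
  dx <- array(0, c(h_in, w_in, cache$C))
  for (c in seq_len(cache$C))
    dx[, , c] <- t(cache$Mh) %*% dy[, , c] %*% cache$Mw
  dx
}

#' Pixel-wise softmax cross-entropy
#'
#' @param logits H x W x K array.
#' @param labels H x W integer matrix with classes 0..K-1.
#' @return List with `loss` (mean over pixels) and `dlogits` (same shape
#'   as `logits`).
#' @keywords internal
softmax_ce <- function(logits, labels) {
  d <- dim(logits); np <- d[1] * d[2]; K <- d[3]
  lm <- logits; dim(lm) <- c(np, K)
  lm <- lm - apply(lm, 1, max)
  el <- exp(lm)
  p <- el / rowSums(el)
  idx <- cbind(seq_len(np), as.vector(labels) + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dp <- p
  dp[idx] <- dp[idx] - 1
  list(loss = loss, dlogits = array(dp / np, d), prob = array(p, d))
}
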