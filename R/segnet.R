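#' Network configuration
#'
#' Describes the attention-augmented U-Net: an encoder of 3x3
#' convolution blocks whose resolution is halved `encoder_stages` times
#' (output stride 16 for the default 4 stages), a deepest block of three
#' 3x3 convolutions dilated at `dilation_rate` (receptive-field growth
#' without further downsampling), an ASPP head whose image-level branch
#' uses sub-region average pooling, and a decoder that repeatedly
#' upsamples, adds a 3x3-convolved low-level skip feature, merges with a
#' 3x3 convolution, and recalibrates the merged feature with fused
#' SAP/CE channel attention — one attention block per merge — before
#' restoring full resolution bilinearly.
#'
#' @param in_channels Input channels (1 for grayscale CT).
#' @param n_classes Output classes including background (k + 1).
#' @param base_width Channels at the first encoder stage; stage s uses
#'   `base_width * 2^(s-1)`.
#' @param encoder_stages Number of resolution halvings (default 4, i.e.
#'   output stride 16 at the encoder head).
#' @param dilation_rate Dilation (expansion) rate of the deepest encoder
#'   block (default 2).
#' @param aspp_rates Dilation rates of the parallel 3x3 ASPP branches.
#' @param sap_grid Sub-region pooling grid `c(m, n)` used by the ASPP
#'   image-level branch and the attention blocks.
#' @param reduction_C Squeeze-excite reduction ratio (kept in the config
#'   for the GAP-SE baseline blocks; default 16).
#' @param decoder_merges Encoder stages whose features are merged back
#'   in, listed coarse to fine (strictly decreasing). The default `3`
#'   performs a single merge at 1/4 resolution; `c(3, 2, 1)` gives the
#'   full U-Net-style ladder, which preserves markedly more boundary
#'   detail when the structures of interest are only a few pixels wide.
#' @param pad_inputs If `TRUE`, inputs whose sides are not divisible by
#'   the output stride are zero-padded and the logits cropped back;
#'   if `FALSE` such inputs are an error.
#' @param init_seed Seed for weight initialization.
#' @return An object of class `net_config`.
#' @export
net_config <- function(in_channels = 1L, n_classes = 2L, base_width = 32L,
                       encoder_stages = 4L, dilation_rate = 2L,
                       aspp_rates = c(1L, 2L, 4L), sap_grid = c(2L, 2L),
                       reduction_C = 16L, decoder_merges = NULL,
                       pad_inputs = FALSE, init_seed = 1L) {
  stopifnot(in_channels >= 1, n_classes >= 2, base_width >= 1,
            encoder_stages >= 1, dilation_rate >= 1, length(aspp_rates) >= 1,
            length(sap_grid) == 2, all(sap_grid >= 1), reduction_C >= 1)
  if (is.null(decoder_merges)) decoder_merges <- min(3L, encoder_stages)
  decoder_merges <- as.integer(decoder_merges)
  if (any(decoder_merges < 1) || any(decoder_merges > encoder_stages) ||
      any(diff(decoder_merges) >= 0))
    stop("'decoder_merges' must be strictly decreasing encoder stages ",
         "within 1..encoder_stages", call. = FALSE)
  structure(list(in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 base_width = as.integer(base_width),
                 encoder_stages = as.integer(encoder_stages),
                 dilation_rate = as.integer(dilation_rate),
                 aspp_rates = as.integer(aspp_rates),
                 sap_grid = as.integer(sap_grid),
                 reduction_C = as.integer(reduction_C),
                 decoder_merges = decoder_merges,
                 pad_inputs = isTRUE(pad_inputs),
                 init_seed = as.integer(init_seed)),
            class = "net_config")
}

#' Output stride of a configuration
#' @param cfg A [net_config()].
#' @return Integer ratio of input to encoder-head resolution.
#' @export
output_stride <- function(cfg) 2L^cfg$encoder_stages

# Stage widths: base, 2*base, ..., 2^(S-1)*base.
stage_widths <- function(cfg)
  cfg$base_width * 2L^(seq_len(cfg$encoder_stages) - 1L)

#' Build the segmentation network
#'
#' Allocates and He-initializes every parameter of the architecture
#' described in [net_config()]. Biases start at zero. Each decoder merge
#' stage owns a low-level 3x3 convolution, a merge 3x3 convolution, and
#' an attention block (SAP kernel plus CE channel-expansion weights).
#'
#' @param cfg A [net_config()].
#' @return An object of class `toothseg_net`: a list with `cfg`, `params`
#'   (named list of arrays), and layout bookkeeping.
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "net_config"))
  set.seed(cfg$init_seed)
  w <- stage_widths(cfg)
  S <- cfg$encoder_stages
  head_w <- w[S]
  wa <- 2L * cfg$base_width         # ASPP branch width
  wd <- 2L * cfg$base_width         # decoder width
  p <- list()
  cin <- cfg$in_channels
  for (s in seq_len(S)) {
    p[[paste0("enc", s, "_c1_W")]] <- conv_init(3, 3, cin, w[s])
    p[[paste0("enc", s, "_c1_b")]] <- numeric(w[s])
    p[[paste0("enc", s, "_c2_W")]] <- conv_init(3, 3, w[s], w[s])
    p[[paste0("enc", s, "_c2_b")]] <- numeric(w[s])
    cin <- w[s]
  }
  for (j in 1:3) {                  # dilated head block: three 3x3 convs
    p[[paste0("head_c", j, "_W")]] <- conv_init(3, 3, head_w, head_w)
    p[[paste0("head_c", j, "_b")]] <- numeric(head_w)
  }
  p[["aspp_p1_W"]] <- conv_init(1, 1, head_w, wa)
  p[["aspp_p1_b"]] <- numeric(wa)
  for (r in cfg$aspp_rates) {
    p[[paste0("aspp_d", r, "_W")]] <- conv_init(3, 3, head_w, wa)
    p[[paste0("aspp_d", r, "_b")]] <- numeric(wa)
  }
  p[["aspp_sap_W"]] <- conv_init(1, 1, head_w, wa)
  p[["aspp_sap_b"]] <- numeric(wa)
  n_br <- 2L + length(cfg$aspp_rates)
  p[["aspp_proj_W"]] <- conv_init(1, 1, n_br * wa, wd)
  p[["aspp_proj_b"]] <- numeric(wd)
  m <- cfg$sap_grid[1]; n <- cfg$sap_grid[2]
  for (s in cfg$decoder_merges) {
    p[[paste0("dec", s, "_low_W")]] <- conv_init(3, 3, w[s], wd)
    p[[paste0("dec", s, "_low_b")]] <- numeric(wd)
    p[[paste0("dec", s, "_merge_W")]] <- conv_init(3, 3, wd, wd)
    p[[paste0("dec", s, "_merge_b")]] <- numeric(wd)
    p[[paste0("att", s, "_phi")]] <-
      array(stats::rnorm(m * n * wd, 0, sqrt(2 / (m * n * wd))),
            c(m, n, wd))
    p[[paste0("att", s, "_ce")]] <-
      matrix(stats::rnorm(wd * w[s], 0, sqrt(2 / w[s])), wd, w[s])
  }
  p[["final_W"]] <- conv_init(1, 1, wd, cfg$n_classes)
  p[["final_b"]] <- numeric(cfg$n_classes)
  structure(list(cfg = cfg, params = p,
                 layout = list(widths = w, head_w = head_w,
                               wa = wa, wd = wd)),
            class = "toothseg_net")
}

#' Count trainable parameters
#' @param net A `toothseg_net`.
#' @return Integer number of trainable scalars.
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "toothseg_net"))
  sum(vapply(net$params, length, integer(1)))
}

#' @export
print.toothseg_net <- function(x, ...) {
  cfg <- x$cfg
  cat("toothseg_net: in", cfg$in_channels, "-> classes", cfg$n_classes,
      "| base", cfg$base_width, "| stages", cfg$encoder_stages,
      "(output stride", output_stride(cfg), ")",
      "| dilation", cfg$dilation_rate,
      "| ASPP rates", paste(cfg$aspp_rates, collapse = "/"),
      "| SAP grid", paste(cfg$sap_grid, collapse = "x"),
      "| merges at", paste(cfg$decoder_merges, collapse = ","), "\n")
  cat("parameters:", count_parameters(x), "\n")
  invisible(x)
}

# Gradient of sap_pool: distribute each cell's gradient uniformly over
# the pixels that were averaged.
sap_pool_backward <- function(dpool, H, W, grid) {
  m <- grid[1]; n <- grid[2]; K <- dim(dpool)[3]
  rb <- floor(H * (0:m) / m)
  cb <- floor(W * (0:n) / n)
  dx <- array(0, c(H, W, K))
  for (i in seq_len(m)) for (j in seq_len(n)) {
    rows <- (rb[i] + 1):rb[i + 1]; cols <- (cb[j] + 1):cb[j + 1]
    npix <- length(rows) * length(cols)
    dx[rows, cols, ] <- rep(dpool[i, j, ] / npix, each = npix)
  }
  dx
}

#' Forward pass
#'
#' Runs a single H x W grayscale image (matrix or H x W x C array)
#' through the network. Deterministic: the architecture has no dropout or
#' batch-norm, so repeated calls with the same weights give identical
#' logits.
#'
#' @param net A `toothseg_net`.
#' @param x Input image, values in \[0,1\].
#' @param want One of `"logits"` (default), `"features"` (adds encoder/
#'   decoder intermediates), or `"cache"` (adds everything the backward
#'   pass needs).
#' @return For `"logits"`, an H x W x n_classes array; otherwise a list.
#' @export
net_forward <- function(net, x, want = c("logits", "features", "cache")) {
  want <- match.arg(want)
  cfg <- net$cfg; p <- net$params; ly <- net$layout
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stopifnot(dim(x)[3] == cfg$in_channels)
  os <- output_stride(cfg)
  H0 <- dim(x)[1]; W0 <- dim(x)[2]
  padded <- FALSE
  if (H0 %% os != 0 || W0 %% os != 0) {
    if (!cfg$pad_inputs)
      stop("input size ", H0, "x", W0, " is not divisible by the output ",
           "stride ", os, " (set pad_inputs = TRUE to zero-pad)",
           call. = FALSE)
    Hp <- ceiling(H0 / os) * os; Wp <- ceiling(W0 / os) * os
    xp <- array(0, c(Hp, Wp, dim(x)[3]))
    xp[seq_len(H0), seq_len(W0), ] <- x
    x <- xp; padded <- TRUE
  }
  cc <- list()   # caches
  conv_relu <- function(x, nm, dilation = 1L) {
    cv <- conv2d_forward(x, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]],
                         dilation)
    rl <- relu_forward(cv$out)
    cc[[nm]] <<- list(conv = cv$cache, relu = rl$cache)
    rl$out
  }
  # --- encoder ---
  feats <- vector("list", cfg$encoder_stages)
  h <- x
  for (s in seq_len(cfg$encoder_stages)) {
    h <- conv_relu(h, paste0("enc", s, "_c1"))
    h <- conv_relu(h, paste0("enc", s, "_c2"))
    feats[[s]] <- h
    mp <- maxpool2_forward(h)
    cc[[paste0("pool", s)]] <- mp$cache
    h <- mp$out
  }
  for (j in 1:3)
    h <- conv_relu(h, paste0("head_c", j), dilation = cfg$dilation_rate)
  head <- h
  hh <- dim(head)[1]; hw <- dim(head)[2]
  # --- ASPP ---
  branches <- list(conv_relu(head, "aspp_p1"))
  for (r in cfg$aspp_rates)
    branches <- c(branches, list(conv_relu(head, paste0("aspp_d", r),
                                           dilation = r)))
  sp <- sap_pool(head, pmin(cfg$sap_grid, c(hh, hw)))
  sap_br <- conv_relu(sp, "aspp_sap")
  su <- upsample_forward(sap_br, hh, hw)
  cc[["aspp_sap_up"]] <- su$cache
  cc[["aspp_sap_grid"]] <- pmin(cfg$sap_grid, c(hh, hw))
  branches <- c(branches, list(su$out))
  cat_f <- array(0, c(hh, hw, length(branches) * ly$wa))
  for (b in seq_along(branches))
    cat_f[, , ((b - 1) * ly$wa + 1):(b * ly$wa)] <- branches[[b]]
  h <- conv_relu(cat_f, "aspp_proj")
  aspp <- h
  # --- decoder: one attended merge per configured stage ---
  for (s in cfg$decoder_merges) {
    low <- feats[[s]]
    lh <- dim(low)[1]; lw <- dim(low)[2]
    up <- upsample_forward(h, lh, lw)
    cc[[paste0("dec", s, "_up")]] <- up$cache
    lowc <- conv_relu(low, paste0("dec", s, "_low"))
    merged <- conv_relu(up$out + lowc, paste0("dec", s, "_merge"))
    att <- sap_params(pmin(cfg$sap_grid, c(lh, lw)), K = ly$wd,
                      K_low = dim(low)[3],
                      conv_kernel = p[[paste0("att", s, "_phi")]],
                      ce_weights = p[[paste0("att", s, "_ce")]])
    eps_h <- sap_attention(up$out, att)
    eps_l <- ce_attention(low, att)
    eps_f <- fuse_attention(eps_l, eps_h)
    h <- recalibrate(merged, eps_f)
    cc[[paste0("att", s)]] <- list(grid = att$grid, eps_h = eps_h,
                                   eps_l = eps_l, eps_f = eps_f,
                                   up = up$out, low = low, merged = merged)
  }
  # --- restore resolution ---
  uf <- upsample_forward(h, dim(x)[1], dim(x)[2])
  cc[["final_up"]] <- uf$cache
  fcv <- conv2d_forward(uf$out, p$final_W, p$final_b)
  cc[["final"]] <- fcv$cache
  logits <- fcv$out
  if (padded) logits <- logits[seq_len(H0), seq_len(W0), , drop = FALSE]
  if (want == "logits") return(logits)
  out <- list(logits = logits, head = head, aspp = aspp, decoder = h,
              encoder_features = feats)
  if (want == "cache") {
    out$cache <- cc
    out$padded <- padded
    out$full_size <- dim(x)[1:2]
    out$orig_size <- c(H0, W0)
  }
  out
}

#' Backward pass
#'
#' Propagates the gradient of a scalar loss with respect to the logits
#' back through the network, returning a named list of parameter
#' gradients matching `net$params`.
#'
#' @param net A `toothseg_net`.
#' @param fw The `"cache"` result of [net_forward()].
#' @param dlogits Gradient at the logits, same shape as the logits.
#' @return Named list of gradients.
#' @export
net_backward <- function(net, fw, dlogits) {
  cfg <- net$cfg; p <- net$params; ly <- net$layout; cc <- fw$cache
  g <- list()
  back_conv_relu <- function(dy, nm) {
    dy <- relu_backward(dy, cc[[nm]]$relu)
    bk <- conv2d_backward(dy, cc[[nm]]$conv)
    g[[paste0(nm, "_W")]] <<- bk$dW
    g[[paste0(nm, "_b")]] <<- bk$db
    bk$dx
  }
  if (fw$padded) {
    dfull <- array(0, c(fw$full_size, dim(dlogits)[3]))
    dfull[seq_len(fw$orig_size[1]), seq_len(fw$orig_size[2]), ] <- dlogits
    dlogits <- dfull
  }
  bk <- conv2d_backward(dlogits, cc$final)
  g$final_W <- bk$dW; g$final_b <- bk$db
  drec <- upsample_backward(bk$dx, cc$final_up)
  # --- decoder backward, finest merge first ---
  dlow_into_encoder <- list()
  for (s in rev(cfg$decoder_merges)) {
    at <- cc[[paste0("att", s)]]
    eps_f <- as.numeric(at$eps_f)
    dmerged <- sweep(drec, 3, eps_f, `*`)
    deps_f <- vapply(seq_along(eps_f),
                     function(k) sum(drec[, , k] * at$merged[, , k]),
                     numeric(1))
    # high branch: eps_h = sigmoid(sum_ab phi_r[a,b] * cellsum[a,b])
    eh <- as.numeric(at$eps_h)
    dpre_h <- deps_f * eh * (1 - eh)
    fhat <- sap_pool(at$up, at$grid)
    cell_sums <- apply(fhat, c(1, 2), sum)
    phi <- p[[paste0("att", s, "_phi")]]
    dphi <- array(0, dim(phi))
    for (r in seq_along(dpre_h)) dphi[, , r] <- dpre_h[r] * cell_sums
    g[[paste0("att", s, "_phi")]] <- dphi
    dcell <- matrix(0, at$grid[1], at$grid[2])
    for (r in seq_along(dpre_h)) dcell <- dcell + dpre_h[r] * phi[, , r]
    dfhat <- array(rep(dcell, dim(fhat)[3]), dim(fhat))
    dup_att <- sap_pool_backward(dfhat, dim(at$up)[1], dim(at$up)[2],
                                 at$grid)
    # low branch: eps_l = sigmoid(Wce %*% v), v = per-channel cell mean
    el <- as.numeric(at$eps_l)
    dpre_l <- deps_f * el * (1 - el)
    pooled_low <- sap_pool(at$low, at$grid)
    v <- apply(pooled_low, 3, mean)
    g[[paste0("att", s, "_ce")]] <- outer(dpre_l, v)
    wce <- p[[paste0("att", s, "_ce")]]
    dv <- as.vector(crossprod(wce, dpre_l))
    dpool_low <- array(rep(dv / prod(at$grid), each = prod(at$grid)),
                       dim(pooled_low))
    dlow_att <- sap_pool_backward(dpool_low, dim(at$low)[1],
                                  dim(at$low)[2], at$grid)
    # merge and skip convolutions
    dmerged0 <- back_conv_relu(dmerged, paste0("dec", s, "_merge"))
    dup <- dmerged0 + dup_att
    dlow_into_encoder[[as.character(s)]] <-
      back_conv_relu(dmerged0, paste0("dec", s, "_low")) + dlow_att
    drec <- upsample_backward(dup, cc[[paste0("dec", s, "_up")]])
  }
  daspp <- drec
  # --- ASPP backward ---
  dcat <- back_conv_relu(daspp, "aspp_proj")
  wa <- ly$wa
  n_br <- 2L + length(cfg$aspp_rates)
  dhead <- back_conv_relu(dcat[, , 1:wa, drop = FALSE], "aspp_p1")
  for (i in seq_along(cfg$aspp_rates)) {
    r <- cfg$aspp_rates[i]
    sl <- dcat[, , (i * wa + 1):((i + 1) * wa), drop = FALSE]
    dhead <- dhead + back_conv_relu(sl, paste0("aspp_d", r))
  }
  dsap_up <- dcat[, , ((n_br - 1) * wa + 1):(n_br * wa), drop = FALSE]
  dsap_br <- upsample_backward(dsap_up, cc$aspp_sap_up)
  dsp <- back_conv_relu(dsap_br, "aspp_sap")
  hh <- dim(dhead)[1]; hw <- dim(dhead)[2]
  dhead <- dhead + sap_pool_backward(dsp, hh, hw, cc$aspp_sap_grid)
  # --- encoder backward ---
  dh <- dhead
  for (j in 3:1) dh <- back_conv_relu(dh, paste0("head_c", j))
  for (s in cfg$encoder_stages:1) {
    dh <- maxpool2_backward(dh, cc[[paste0("pool", s)]])
    extra <- dlow_into_encoder[[as.character(s)]]
    if (!is.null(extra)) dh <- dh + extra
    dh <- back_conv_relu(dh, paste0("enc", s, "_c2"))
    dh <- back_conv_relu(dh, paste0("enc", s, "_c1"))
  }
  g
}

#' Save a network checkpoint
#'
#' Single-file checkpoint with a versioned header (format version,
#' configuration, parameters).
#'
#' @param net A `toothseg_net`.
#' @param path Destination file.
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "toothseg_net"))
  saveRDS(list(format = "toothseg-checkpoint", version = 1L,
               cfg = net$cfg, params = net$params, layout = net$layout),
          path)
  invisible(path)
}

#' Load a network checkpoint
#' @param path File written by [save_checkpoint()].
#' @return A `toothseg_net`.
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "toothseg-checkpoint"))
    stop("not a toothseg checkpoint: ", path, call. = FALSE)
  structure(list(cfg = x$cfg, params = x$params, layout = x$layout),
            class = "toothseg_net")
}
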