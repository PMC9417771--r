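#' Augmentation configuration
#'
#' Parameters for the four augmentation operators applied to image/mask
#' pairs — random crop, flip, gray-level perturbation, and 3-vertex affine
#' shape perturbation — and for the offline dataset enlargement.
#'
#' @param crop_fraction Side fraction of the random crop window, in (0,1].
#' @param flip_modes Subset of `c("horizontal", "vertical")` to draw from.
#' @param gray_sigma Scale of the additive zero-mean Gaussian gray
#'   perturbation, >= 0.
#' @param vertex_shift_fraction Maximum random displacement of each of the
#'   three reference corners (upper-left, upper-right, lower-left), as a
#'   fraction of the image side, in \[0, 0.5).
#' @param enlargement_factor Integer >= 1: each input pair yields this many
#'   output pairs (the original plus `factor - 1` augmented variants).
#' @param seed Integer seed for per-sample augmentation streams.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(crop_fraction = 0.9,
                           flip_modes = c("horizontal", "vertical"),
                           gray_sigma = 0.02,
                           vertex_shift_fraction = 0.1,
                           enlargement_factor = 3L,
                           seed = 1L) {
  if (!is.numeric(crop_fraction) || crop_fraction <= 0 || crop_fraction > 1)
    stop("'crop_fraction' must be in (0,1]", call. = FALSE)
  if (length(flip_modes) &&
      !all(flip_modes %in% c("horizontal", "vertical")))
    stop("'flip_modes' must be a subset of horizontal/vertical",
         call. = FALSE)
  if (gray_sigma < 0) stop("'gray_sigma' must be >= 0", call. = FALSE)
  if (vertex_shift_fraction < 0 || vertex_shift_fraction >= 0.5)
    stop("'vertex_shift_fraction' must be in [0, 0.5)", call. = FALSE)
  if (enlargement_factor < 1 ||
      enlargement_factor != round(enlargement_factor))
    stop("'enlargement_factor' must be an integer >= 1", call. = FALSE)
  structure(list(crop_fraction = crop_fraction,
                 flip_modes = flip_modes,
                 gray_sigma = gray_sigma,
                 vertex_shift_fraction = vertex_shift_fraction,
                 enlargement_factor = as.integer(enlargement_factor),
                 seed = as.integer(seed)),
            class = "augment_config")
}

#' Global histogram equalization
#'
#' Maps each gray level through the image's own cumulative distribution:
#' pixels are binned into `levels` equal-width bins over \[0,1\] and each
#' pixel is replaced by the CDF value of its bin. The mapping is monotone
#' non-decreasing, so gray-level order is preserved. A constant image has a
#' degenerate histogram and is returned unchanged.
#'
#' @param img Numeric matrix in \[0,1\].
#' @param levels Number of gray bins (default 256).
#' @return Equalized matrix in \[0,1\].
#' @export
equalize_hist <- function(img, levels = 256L) {
  stopifnot(is.matrix(img), length(img) > 0)
  if (max(img) == min(img)) return(img)
  q <- floor(pmin(pmax(img, 0), 1) * levels)
  q[q == levels] <- levels - 1
  cdf <- cumsum(tabulate(q + 1L, levels)) / length(img)
  matrix(cdf[q + 1L], nrow(img), ncol(img))
}

# Per-tile clipped-histogram CDF lookup table over `levels` bins.
# A degenerate tile (all mass in one bin) maps through the identity so
# that constant regions are left untouched.
clahe_tile_lut <- function(vals, levels, clip_limit) {
  h <- tabulate(vals + 1L, levels)
  if (max(h) == length(vals)) {
    return((seq_len(levels) - 0.5) / levels)   # identity LUT at bin centers
  }
  if (is.finite(clip_limit)) {
    cap <- clip_limit * length(vals) / levels
    excess <- sum(pmax(h - cap, 0))
    h <- pmin(h, cap) + excess / levels
  }
  cumsum(h) / sum(h)
}

#' Contrast-limited adaptive histogram equalization
#'
#' The image is divided into a `tile_grid` of near-equal tiles; each tile's
#' histogram is clipped at `clip_limit` times the uniform bin height (the
#' excess redistributed evenly) and turned into a CDF lookup table. Each
#' pixel is mapped through a bilinear interpolation of the four nearest
#' tile tables, which avoids tile-boundary seams. With a single tile and an
#' infinite clip limit this reduces exactly to [equalize_hist()].
#'
#' @param img Numeric matrix in \[0,1\].
#' @param tile_grid Integer vector `c(rows, cols)` of tile counts.
#' @param clip_limit Histogram clip factor (multiple of the uniform bin
#'   height); `Inf` disables clipping.
#' @param levels Number of gray bins.
#' @return Equalized matrix in \[0,1\].
#' @export
equalize_adaptive <- function(img, tile_grid = c(8L, 8L), clip_limit = 2,
                              levels = 256L) {
  stopifnot(is.matrix(img), length(img) > 0)
  H <- nrow(img); W <- ncol(img)
  tr <- tile_grid[1]; tc <- tile_grid[2]
  if (H / tr < 1 || W / tc < 1) {
    warning("tile grid exceeds image size; falling back to global HE")
    return(equalize_hist(img, levels))
  }
  if (max(img) == min(img)) return(img)
  q <- floor(pmin(pmax(img, 0), 1) * levels)
  q[q == levels] <- levels - 1
  q <- matrix(as.integer(q), H, W)
  # tile boundaries and centers
  rb <- floor(H * (0:tr) / tr)   # row boundaries, tile i covers (rb[i], rb[i+1]]
  cb <- floor(W * (0:tc) / tc)
  rcen <- (rb[-1] + rb[-(tr + 1)] + 1) / 2
  ccen <- (cb[-1] + cb[-(tc + 1)] + 1) / 2
  luts <- array(0, c(levels, tr, tc))
  for (i in seq_len(tr)) for (j in seq_len(tc)) {
    vals <- q[(rb[i] + 1):rb[i + 1], (cb[j] + 1):cb[j + 1]]
    luts[, i, j] <- clahe_tile_lut(as.integer(vals), levels, clip_limit)
  }
  # per-pixel bilinear blend of the four surrounding tile LUTs
  row_lo <- pmin(pmax(findInterval(seq_len(H), rcen), 1L), tr)
  row_hi <- pmin(row_lo + as.integer(seq_len(H) > rcen[row_lo]), tr)
  wr <- ifelse(row_hi > row_lo,
               (seq_len(H) - rcen[row_lo]) / (rcen[row_hi] - rcen[row_lo]), 0)
  col_lo <- pmin(pmax(findInterval(seq_len(W), ccen), 1L), tc)
  col_hi <- pmin(col_lo + as.integer(seq_len(W) > ccen[col_lo]), tc)
  wc <- ifelse(col_hi > col_lo,
               (seq_len(W) - ccen[col_lo]) / (ccen[col_hi] - ccen[col_lo]), 0)
  ri <- rep(seq_len(H), W)          # pixel row index, column-major order
  ci <- rep(seq_len(W), each = H)
  bn <- as.vector(q) + 1L
  v_ll <- luts[cbind(bn, row_lo[ri], col_lo[ci])]
  v_hl <- luts[cbind(bn, row_hi[ri], col_lo[ci])]
  v_lh <- luts[cbind(bn, row_lo[ri], col_hi[ci])]
  v_hh <- luts[cbind(bn, row_hi[ri], col_hi[ci])]
  WR <- wr[ri]; WC <- wc[ci]
  out <- (1 - WC) * ((1 - WR) * v_ll + WR * v_hl) +
    WC * ((1 - WR) * v_lh + WR * v_hh)
  matrix(out, H, W)
}

#' Min-max intensity normalization to \[0,1\]
#'
#' Affine rescale sending the image minimum to 0 and maximum to 1. A
#' constant image maps to 0.5 everywhere by convention (keeps the range
#' contract without dividing by zero).
#'
#' @param img Numeric matrix.
#' @return Matrix with min 0 and max 1 (or all 0.5 if constant).
#' @export
normalize_image <- function(img) {
  stopifnot(is.matrix(img), length(img) > 0)
  lo <- min(img); hi <- max(img)
  if (hi == lo) return(matrix(0.5, nrow(img), ncol(img)))
  (img - lo) / (hi - lo)
}

# Bilinear (image) / nearest-neighbor (mask) resize via EBImage.
resize_image <- function(img, h, w) {
  if (nrow(img) == h && ncol(img) == w) return(img)
  as.matrix(EBImage::resize(img, w = h, h = w, filter = "bilinear"))
}

resize_mask <- function(mask, h, w) {
  if (nrow(mask) == h && ncol(mask) == w) return(mask)
  m <- as.matrix(EBImage::resize(mask, w = h, h = w, filter = "none"))
  matrix(as.integer(round(m)), h, w)
}

#' Random crop of an image/mask pair
#'
#' Draws one square window of side `crop_fraction * side` uniformly, crops
#' image and mask identically, and resizes both back to the input size
#' (bilinear for the image, nearest-neighbor for the mask).
#'
#' @param img Numeric matrix in \[0,1\].
#' @param mask Integer matrix of the same size.
#' @param cfg An [augment_config()].
#' @return A `sample_pair`; `meta` records the window.
#' @export
random_crop <- function(img, mask, cfg) {
  stopifnot(all(dim(img) == dim(mask)))
  H <- nrow(img); W <- ncol(img)
  ch <- max(1L, round(cfg$crop_fraction * H))
  cw <- max(1L, round(cfg$crop_fraction * W))
  top <- sample.int(H - ch + 1L, 1L)
  left <- sample.int(W - cw + 1L, 1L)
  ci <- img[top:(top + ch - 1L), left:(left + cw - 1L), drop = FALSE]
  cm <- mask[top:(top + ch - 1L), left:(left + cw - 1L), drop = FALSE]
  structure(list(image = resize_image(ci, H, W),
                 mask = resize_mask(cm, H, W),
                 meta = list(op = "crop", top = top, left = left,
                             h = ch, w = cw)),
            class = "sample_pair")
}

#' Flip an image/mask pair
#'
#' @param img,mask Matrices of identical size.
#' @param mode `"horizontal"` (reverse columns) or `"vertical"` (reverse
#'   rows); the same reversal is applied to both.
#' @return A `sample_pair`.
#' @export
flip_pair <- function(img, mask, mode = c("horizontal", "vertical")) {
  mode <- match.arg(mode)
  stopifnot(all(dim(img) == dim(mask)))
  if (mode == "horizontal") {
    img <- img[, ncol(img):1, drop = FALSE]
    mask <- mask[, ncol(mask):1, drop = FALSE]
  } else {
    img <- img[nrow(img):1, , drop = FALSE]
    mask <- mask[nrow(mask):1, , drop = FALSE]
  }
  structure(list(image = img, mask = mask, meta = list(op = "flip",
                                                       mode = mode)),
            class = "sample_pair")
}

#' Additive gray-level perturbation
#'
#' Adds zero-mean Gaussian noise of scale `gray_sigma` to the image and
#' clips to \[0,1\]; the mask is never touched.
#'
#' @param img Numeric matrix in \[0,1\].
#' @param cfg An [augment_config()] (uses `gray_sigma`).
#' @return Perturbed matrix.
#' @export
gray_perturb <- function(img, cfg) {
  if (cfg$gray_sigma == 0) return(img)
  pmin(pmax(img + matrix(stats::rnorm(length(img), 0, cfg$gray_sigma),
                         nrow(img), ncol(img)), 0), 1)
}

# Solve the 2D affine map sending three (row, col) source points to three
# target points; returns the 3x2 matrix EBImage::affine expects
# (output coords = [row, col, 1] %*% m).
affine_from_triangle <- function(src, dst) {
  P <- cbind(src, 1)
  d <- det(P)
  if (abs(d) < 1e-8) return(NULL)
  solve(P, dst)
}

#' Three-vertex affine shape perturbation
#'
#' The upper-left, upper-right and lower-left corners of the frame are
#' each displaced by an independent uniform shift of at most
#' `vertex_shift_fraction` of the image side; the unique affine transform
#' sending the original corners to their displaced positions is then
#' applied to the whole image (bilinear) and mask (nearest-neighbor).
#' Regions mapped in from outside the frame are filled with background
#' (gray 0 / class 0). A degenerate (collinear) target triangle is
#' resampled, up to 10 times.
#'
#' @param img,mask Matrices of identical size.
#' @param cfg An [augment_config()] (uses `vertex_shift_fraction`).
#' @return A `sample_pair`; `meta` records the 3x2 transform matrix.
#' @export
shape_perturb <- function(img, mask, cfg) {
  stopifnot(all(dim(img) == dim(mask)))
  H <- nrow(img); W <- ncol(img)
  side <- max(H, W)
  src <- rbind(c(1, 1), c(1, W), c(H, 1))  # upper-left, upper-right, lower-left
  f <- cfg$vertex_shift_fraction
  m <- NULL
  for (try in 1:10) {
    dst <- src + matrix(stats::runif(6, -f, f) * side, 3, 2)
    m <- affine_from_triangle(src, dst)
    if (!is.null(m)) break
  }
  if (is.null(m))
    stop("degenerate target triangle after 10 resampling attempts",
         call. = FALSE)
  if (f == 0) {
    out_img <- img
    out_mask <- mask
  } else {
    out_img <- as.matrix(EBImage::affine(img, m, filter = "bilinear",
                                         bg.col = 0))
    out_mask <- as.matrix(EBImage::affine(mask, m, filter = "none",
                                          bg.col = 0))
    out_mask <- matrix(as.integer(round(out_mask)), H, W)
  }
  structure(list(image = out_img, mask = out_mask,
                 meta = list(op = "shape", transform = m)),
            class = "sample_pair")
}

# One random composition of the four augmentation operators.
augment_once <- function(pair, cfg) {
  img <- pair$image; mask <- pair$mask
  p <- random_crop(img, mask, cfg)
  if (length(cfg$flip_modes) && stats::runif(1) < 0.5) {
    mode <- cfg$flip_modes[sample.int(length(cfg$flip_modes), 1L)]
    p <- flip_pair(p$image, p$mask, mode)
  }
  p$image <- gray_perturb(p$image, cfg)
  shape_perturb(p$image, p$mask, cfg)
}

#' Offline dataset enlargement by augmentation
#'
#' For an enlargement factor f, each input pair contributes f output pairs:
#' the original plus f−1 freshly augmented variants, each produced by a
#' random composition of random crop, flip, gray perturbation, and shape
#' perturbation. Variant `j` of input `i` uses the deterministic seed
#' `slice_seed(cfg$seed, i * factor + j)`, so the enlarged set is
#' reproducible sample by sample.
#'
#' @param pairs List of `sample_pair` objects.
#' @param cfg An [augment_config()].
#' @return List of `length(pairs) * enlargement_factor` sample pairs.
#' @export
enlarge_dataset <- function(pairs, cfg) {
  stopifnot(inherits(cfg, "augment_config"))
  f <- cfg$enlargement_factor
  out <- vector("list", length(pairs) * f)
  k <- 0L
  for (i in seq_along(pairs)) {
    k <- k + 1L
    out[[k]] <- pairs[[i]]
    if (f > 1L) for (j in seq_len(f - 1L)) {
      set.seed(slice_seed(cfg$seed, i * f + j))
      k <- k + 1L
      out[[k]] <- augment_once(pairs[[i]], cfg)
    }
  }
  out
}

#' Preprocess one image for the network
#'
#' Histogram equalization (global or adaptive) followed by min-max
#' normalization to \[0,1\], the intensity contract every network input
#' satisfies.
#'
#' @param img Numeric matrix.
#' @param method `"he"`, `"ahe"`, or `"none"`.
#' @param tile_grid,clip_limit CLAHE parameters (used when
#'   `method = "ahe"`).
#' @return Preprocessed matrix in \[0,1\].
#' @export
preprocess_image <- function(img, method = c("ahe", "he", "none"),
                             tile_grid = c(8L, 8L), clip_limit = 2) {
  method <- match.arg(method)
  out <- switch(method,
                he = equalize_hist(img),
                ahe = equalize_adaptive(img, tile_grid, clip_limit),
                none = img)
  normalize_image(out)
}
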