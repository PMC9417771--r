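#' Configuration for the synthetic tooth phantom generator
#'
#' The phantom emulates the statistical structure of axial dental CT slices:
#' teeth whose gray level is close to the surrounding tissue (low contrast),
#' blurred tooth/tissue boundaries, and gray-level variation both between
#' teeth and, through blur and noise, within a tooth. Teeth are rendered as
#' two arcs of rotated ellipses ("upper" and "lower" rows of a dental arch),
#' each filled with its own gray level drawn from
#' `N(tooth_gray_mean, tooth_gray_jitter^2)`, composited over a uniform
#' tissue background, Gaussian-blurred, and corrupted with additive noise.
#' The ground-truth mask marks the unblurred elliptical supports.
#'
#' @param image_size Side length of the square slice in pixels.
#' @param n_teeth Teeth per slice: a single count or a length-2 inclusive
#'   range from which the count is drawn uniformly.
#' @param tooth_gray_mean Mean tooth gray level, in (0,1).
#' @param tooth_gray_jitter Standard deviation of per-tooth gray levels
#'   (inter-tooth variation), >= 0.
#' @param tissue_gray_mean Background tissue gray level, in (0,1). May be
#'   close to `tooth_gray_mean`; low contrast is the intended regime.
#' @param blur_sigma Gaussian blur standard deviation in pixels (boundary
#'   blurring), >= 0.
#' @param noise_sigma Additive zero-mean Gaussian noise scale, >= 0.
#' @param instance_labels If `TRUE`, each tooth gets its own mask label
#'   (1..n); otherwise the mask is binary (tooth = 1).
#' @param teeth Optional data frame overriding the random arch layout, with
#'   columns `cy`, `cx` (center, pixels), `a`, `b` (semi-axes, pixels),
#'   `theta` (rotation, radians) and optionally `gray`. Used to place teeth
#'   at known positions.
#' @param seed Integer seed; identical seed and configuration give
#'   bitwise-identical output.
#' @return An object of class `phantom_config`.
#' @export
#' @examples
#' cfg <- phantom_config(image_size = 128, seed = 7)
#' sp <- generate_slice(cfg)
#' table(sp$mask)
phantom_config <- function(image_size = 512L,
                           n_teeth = c(8L, 14L),
                           tooth_gray_mean = 0.65,
                           tooth_gray_jitter = 0.08,
                           tissue_gray_mean = 0.45,
                           blur_sigma = 1.5,
                           noise_sigma = 0.05,
                           instance_labels = FALSE,
                           teeth = NULL,
                           seed = 1L) {
  check_scalar_in <- function(x, nm, lo, hi) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= lo || x >= hi)
      stop(sprintf("'%s' must be a single number in (%g,%g)", nm, lo, hi),
           call. = FALSE)
  }
  check_nonneg <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
      stop(sprintf("'%s' must be a single non-negative number", nm),
           call. = FALSE)
  }
  if (!is.numeric(image_size) || length(image_size) != 1L ||
      image_size < 8 || image_size != round(image_size))
    stop("'image_size' must be a single integer >= 8", call. = FALSE)
  if (!is.numeric(n_teeth) || !length(n_teeth) %in% 1:2 ||
      any(n_teeth < 0) || any(n_teeth != round(n_teeth)))
    stop("'n_teeth' must be a non-negative count or range", call. = FALSE)
  check_scalar_in(tooth_gray_mean, "tooth_gray_mean", 0, 1)
  check_scalar_in(tissue_gray_mean, "tissue_gray_mean", 0, 1)
  check_nonneg(tooth_gray_jitter, "tooth_gray_jitter")
  check_nonneg(blur_sigma, "blur_sigma")
  check_nonneg(noise_sigma, "noise_sigma")
  structure(list(image_size = as.integer(image_size),
                 n_teeth = as.integer(n_teeth),
                 tooth_gray_mean = tooth_gray_mean,
                 tooth_gray_jitter = tooth_gray_jitter,
                 tissue_gray_mean = tissue_gray_mean,
                 blur_sigma = blur_sigma,
                 noise_sigma = noise_sigma,
                 instance_labels = isTRUE(instance_labels),
                 teeth = teeth,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("phantom_config:", x$image_size, "x", x$image_size,
      "| teeth", paste(x$n_teeth, collapse = "-"),
      "| tooth", x$tooth_gray_mean, "+/-", x$tooth_gray_jitter,
      "| tissue", x$tissue_gray_mean,
      "| blur", x$blur_sigma, "| noise", x$noise_sigma,
      "| seed", x$seed, "\n")
  invisible(x)
}

#' Rasterize a rotated ellipse
#'
#' Logical mask of pixels whose centers satisfy the rotated-ellipse
#' inequality. Pixel centers are at integer coordinates (row, col),
#' 1-based.
#'
#' @param size Image side length.
#' @param cy,cx Ellipse center (row, column), pixels.
#' @param a,b Semi-axis lengths along the ellipse's own axes, pixels.
#' @param theta Rotation angle in radians.
#' @return A `size` x `size` logical matrix.
#' @keywords internal
ellipse_mask <- function(size, cy, cx, a, b, theta) {
  yy <- matrix(seq_len(size), size, size) - cy          # row offsets
  xx <- matrix(seq_len(size), size, size, byrow = TRUE) - cx
  u <- yy * cos(theta) + xx * sin(theta)
  v <- -yy * sin(theta) + xx * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# Random dental-arch layout: two offset arcs of ellipses spanning the
# lower-front part of the field of view, mimicking an axial jaw section.
phantom_arch_layout <- function(size, n_teeth) {
  if (n_teeth == 0L) {
    return(data.frame(cy = numeric(0), cx = numeric(0), a = numeric(0),
                      b = numeric(0), theta = numeric(0)))
  }
  n_outer <- ceiling(n_teeth / 2)
  n_inner <- n_teeth - n_outer
  arc_cy <- 0.62 * size
  arc_cx <- 0.50 * size
  rows <- list(list(n = n_outer, r = 0.33 * size),
               list(n = n_inner, r = 0.22 * size))
  out <- lapply(rows, function(row) {
    if (row$n == 0L) return(NULL)
    # angles spread over the upper-facing arc, jittered
    ang <- seq(pi + 0.35, 2 * pi - 0.35, length.out = row$n + 2)[-c(1, row$n + 2)]
    if (row$n == 1L) ang <- 1.5 * pi
    ang <- ang + stats::runif(row$n, -0.04, 0.04)
    data.frame(
      cy = arc_cy + row$r * sin(ang) + stats::runif(row$n, -1.5, 1.5),
      cx = arc_cx + row$r * cos(ang) + stats::runif(row$n, -1.5, 1.5),
      a = stats::runif(row$n, 0.050, 0.080) * size,   # radial semi-axis
      b = stats::runif(row$n, 0.030, 0.048) * size,   # tangential semi-axis
      theta = (ang - 1.5 * pi) + stats::runif(row$n, -0.15, 0.15)
    )
  })
  do.call(rbind, out)
}

#' Generate one synthetic tooth-CT slice with its ground-truth mask
#'
#' @param config A [phantom_config()].
#' @return A list of class `sample_pair` with elements `image` (numeric
#'   matrix in \[0,1\]), `mask` (integer matrix; 0 = background), and
#'   `meta` (the tooth parameters actually drawn).
#' @export
generate_slice <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  size <- config$image_size
  if (!is.null(config$teeth)) {
    teeth <- config$teeth
    n <- nrow(teeth)
  } else {
    n <- if (length(config$n_teeth) == 2L) {
      config$n_teeth[1] + floor(stats::runif(1) *
                                (config$n_teeth[2] - config$n_teeth[1] + 1L))
    } else config$n_teeth
    teeth <- phantom_arch_layout(size, n)
  }
  img <- matrix(config$tissue_gray_mean, size, size)
  mask <- matrix(0L, size, size)
  grays <- if (!is.null(teeth$gray)) teeth$gray else
    stats::rnorm(n, config$tooth_gray_mean, config$tooth_gray_jitter)
  grays <- pmin(pmax(grays, 0.02), 0.98)
  if (n > 0) for (t in seq_len(n)) {
    supp <- ellipse_mask(size, teeth$cy[t], teeth$cx[t],
                         teeth$a[t], teeth$b[t], teeth$theta[t])
    img[supp] <- grays[t]
    mask[supp] <- if (config$instance_labels) t else 1L
  }
  if (config$blur_sigma > 0)
    img <- as.matrix(EBImage::gblur(img, sigma = config$blur_sigma))
  if (config$noise_sigma > 0)
    img <- img + matrix(stats::rnorm(size * size, 0, config$noise_sigma),
                        size, size)
  img <- pmin(pmax(img, 0), 1)
  meta <- teeth
  if (n > 0) meta$gray <- grays
  structure(list(image = img, mask = mask, meta = meta),
            class = "sample_pair")
}

#' @export
print.sample_pair <- function(x, ...) {
  cat("sample_pair:", nrow(x$image), "x", ncol(x$image),
      "| classes:", paste(sort(unique(as.integer(x$mask))), collapse = ","),
      "| foreground fraction:", signif(mean(x$mask > 0), 3), "\n")
  invisible(x)
}

#' Deterministic per-slice seed derived from a master seed
#'
#' Multiplicative-congruential mix kept below 2^31 so every derived seed is
#' a valid R integer seed. Distinct (seed, index) pairs map to distinct
#' streams for all practical dataset sizes.
#'
#' @param master_seed Integer master seed.
#' @param index Slice index (1-based).
#' @return A single integer seed.
#' @export
slice_seed <- function(master_seed, index) {
  m <- 2147483647
  s <- ((abs(as.numeric(master_seed)) %% 65536) * 40503 +
        as.numeric(index) * 12347 + 7919) %% m
  as.integer(s)
}

#' Generate a phantom dataset on disk
#'
#' Writes `n_train + n_val` image/mask pairs as 8-bit grayscale PNGs under
#' `out_dir/images` and `out_dir/masks` (shared zero-padded stems), plus a
#' TSV manifest (`stem<TAB>split`) recording split membership. Slice `i`
#' uses the seed `slice_seed(config$seed, i)`, so regeneration with the
#' same master seed is byte-identical and individual slices can be
#' re-created in isolation.
#'
#' @param config A [phantom_config()]; its `seed` is the master seed.
#' @param n_train,n_val Number of training / validation slices (>= 0).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest as a data frame with columns `stem`,
#'   `split`.
#' @export
generate_dataset <- function(config, n_train, n_val, out_dir) {
  stopifnot(inherits(config, "phantom_config"),
            n_train >= 0, n_val >= 0)
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  n <- n_train + n_val
  split <- rep(c("train", "val"), c(n_train, n_val))
  stem <- sprintf("slice_%05d", seq_len(n))
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$seed <- slice_seed(config$seed, i)
    sp <- generate_slice(cfg_i)
    write_gray_png(sp$image, file.path(out_dir, "images",
                                       paste0(stem[i], ".png")))
    write_mask_png(sp$mask, file.path(out_dir, "masks",
                                      paste0(stem[i], ".png")))
  }
  manifest <- data.frame(stem = stem, split = split,
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
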