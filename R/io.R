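#' Write a grayscale image as 8-bit PNG
#'
#' Values are clipped to \[0,1\] and quantized to 8 bits.
#'
#' @param img Numeric matrix in \[0,1\].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_gray_png <- function(img, path) {
  stopifnot(is.matrix(img))
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Write a label mask as 8-bit PNG with raw class indices
#'
#' Class indices 0..255 are stored directly as 8-bit gray values (not
#' palette colors), so metrics computed after a round trip are lossless.
#'
#' @param mask Integer matrix of class labels in 0..255.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.matrix(mask), all(mask >= 0), all(mask <= 255))
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Read a grayscale image from PNG
#'
#' RGB(A) input is converted to grayscale by the Rec. 601 luminance
#' weights, with a warning.
#'
#' @param path PNG file path.
#' @return Numeric matrix in \[0,1\].
#' @export
read_gray_png <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) {
    warning("RGB input '", basename(path),
            "' converted to grayscale by luminance")
    x <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
  }
  x
}

#' Read a label mask from PNG
#'
#' @param path PNG file path written by [write_mask_png()].
#' @return Integer matrix of class labels.
#' @export
read_mask_png <- function(path) {
  if (!file.exists(path)) stop("cannot read mask: ", path, call. = FALSE)
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  m <- matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
  m
}

#' Read an image/mask pair
#'
#' Loads the grayscale image (normalized to \[0,1\] by bit depth) and the
#' integer-coded mask, and checks that their spatial dimensions agree.
#'
#' @param image_path Path to the grayscale PNG image.
#' @param mask_path Path to the class-index PNG mask.
#' @return A `sample_pair` (list with `image`, `mask`, `meta`).
#' @export
read_pair <- function(image_path, mask_path) {
  img <- read_gray_png(image_path)
  mask <- read_mask_png(mask_path)
  if (!all(dim(img) == dim(mask)))
    stop(sprintf("image/mask size mismatch: '%s' is %dx%d but '%s' is %dx%d",
                 image_path, nrow(img), ncol(img),
                 mask_path, nrow(mask), ncol(mask)), call. = FALSE)
  structure(list(image = img, mask = mask,
                 meta = list(image_path = image_path, mask_path = mask_path)),
            class = "sample_pair")
}

#' Load a dataset split written by [generate_dataset()]
#'
#' @param dir Dataset directory containing `images/`, `masks/` and
#'   `manifest.tsv`.
#' @param split One of "train", "val", or "all".
#' @return List of `sample_pair` objects.
#' @export
load_dataset <- function(dir, split = c("all", "train", "val")) {
  split <- match.arg(split)
  mf <- file.path(dir, "manifest.tsv")
  if (!file.exists(mf)) stop("no manifest.tsv under ", dir, call. = FALSE)
  manifest <- utils::read.table(mf, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  if (split != "all") manifest <- manifest[manifest$split == split, ]
  lapply(manifest$stem, function(s)
    read_pair(file.path(dir, "images", paste0(s, ".png")),
              file.path(dir, "masks", paste0(s, ".png"))))
}
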