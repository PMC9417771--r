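#' Pixel confusion matrix
#'
#' A (k+1) x (k+1) table of pixel counts over the k+1 classes (k
#' foreground classes plus background 0). Entry (i, j) counts pixels of
#' true class i predicted as class j, so diagonal entries are the
#' correctly segmented counts n_ii and off-diagonal row/column entries
#' are the n_ij / n_ji confusions.
#'
#' @param k Number of foreground classes (>= 1).
#' @return A zero-initialized `confusion_matrix`.
#' @export
confusion_matrix <- function(k) {
  stopifnot(k >= 1)
  structure(matrix(0, k + 1L, k + 1L,
                   dimnames = list(truth = 0:k, pred = 0:k)),
            k = as.integer(k), class = "confusion_matrix")
}

#' Accumulate pixel counts into a confusion matrix
#'
#' Accumulation is associative over images: summing per-image matrices
#' equals tallying the concatenated pixels.
#'
#' @param cm A [confusion_matrix()].
#' @param truth,pred Integer matrices of identical shape with labels in
#'   0..k.
#' @return The updated `confusion_matrix`.
#' @export
cm_accumulate <- function(cm, truth, pred) {
  stopifnot(inherits(cm, "confusion_matrix"),
            all(dim(truth) == dim(pred)))
  k <- attr(cm, "k")
  if (any(truth < 0 | truth > k) || any(pred < 0 | pred > k))
    stop("labels out of range 0..", k, call. = FALSE)
  idx <- as.integer(truth) * (k + 1L) + as.integer(pred) + 1L
  counts <- tabulate(idx, (k + 1L)^2)
  new <- cm + matrix(counts, k + 1L, k + 1L, byrow = TRUE)
  attributes(new) <- attributes(cm)
  new
}

# Per-class pixel accuracy and IoU with NA for undefined classes.
per_class_stats <- function(cm) {
  k <- attr(cm, "k")
  m <- unclass(cm)
  row_s <- rowSums(m); col_s <- colSums(m); diag_s <- diag(m)
  pa <- ifelse(row_s > 0, diag_s / row_s, NA_real_)
  union <- row_s + col_s - diag_s
  iou <- ifelse(union > 0, diag_s / union, NA_real_)
  data.frame(class = 0:k, pixels = row_s, pa = pa, iou = iou,
             row.names = NULL)
}

#' Mean pixel accuracy (MPA)
#'
#' Per-class fraction of correctly segmented pixels, averaged over
#' classes: `mean_i( n_ii / sum_j n_ij )`. Classes with no ground-truth
#' pixels (empty rows) are undefined (0/0) and excluded from the average,
#' the standard semantic-segmentation convention.
#'
#' @param cm A [confusion_matrix()] with at least one counted pixel.
#' @return A fraction in \[0,1\].
#' @export
mpa <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  st <- per_class_stats(cm)
  mean(st$pa, na.rm = TRUE)
}

#' Mean intersection over union (MIoU)
#'
#' Per-class ratio of intersection to union,
#' `n_ii / (sum_j n_ij + sum_j n_ji - n_ii)`, averaged over classes.
#' Classes absent from both truth and prediction (empty union) are
#' undefined and excluded from the average.
#'
#' @param cm A [confusion_matrix()] with at least one counted pixel.
#' @return A fraction in \[0,1\].
#' @export
miou <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  st <- per_class_stats(cm)
  mean(st$iou, na.rm = TRUE)
}

#' Evaluate predictions against ground truth
#'
#' Pools one confusion matrix over all pairs (whole-set pooling, not
#' per-image averaging) and reports per-class pixel accuracy and IoU plus
#' the MPA and MIoU summaries.
#'
#' @param truths,preds Lists of integer label matrices (aligned).
#' @param k Number of foreground classes.
#' @return List with `per_class` (data frame), `mpa`, `miou`, and the
#'   pooled `confusion` matrix.
#' @export
evaluate_masks <- function(truths, preds, k = 1L) {
  stopifnot(length(truths) == length(preds), length(truths) >= 1)
  cm <- confusion_matrix(k)
  for (i in seq_along(truths)) cm <- cm_accumulate(cm, truths[[i]], preds[[i]])
  list(per_class = per_class_stats(cm), mpa = mpa(cm), miou = miou(cm),
       confusion = cm)
}
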