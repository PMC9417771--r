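#' Training configuration
#'
#' Optimization settings: stochastic gradient descent with momentum 0.9
#' and weight decay 1e-4, a polynomial learning-rate schedule
#' `lr0 * (1 - iter/max_iter)^power` with lr0 = 8e-3 and power = 0.9, and
#' a fixed budget of 800 iterations (optimizer steps). Loss is pixel-wise
#' softmax cross-entropy.
#'
#' @param lr0 Initial learning rate.
#' @param momentum SGD momentum coefficient.
#' @param weight_decay L2 weight-decay rate (added to the gradient).
#' @param power Polynomial decay exponent.
#' @param max_iter Total optimizer steps.
#' @param batch_size Samples per step.
#' @param seed Seed controlling initialization-independent training
#'   randomness (batch order).
#' @param loss Loss identifier; only `"cross_entropy"` is built in.
#' @param val_every Validate every this many iterations (`Inf` = only at
#'   the end).
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr0 = 8e-3, momentum = 0.9, weight_decay = 1e-4,
                         power = 0.9, max_iter = 800L, batch_size = 8L,
                         seed = 1L, loss = "cross_entropy",
                         val_every = Inf) {
  stopifnot(lr0 >= 0, momentum >= 0, momentum < 1, weight_decay >= 0,
            power > 0, max_iter >= 1, batch_size >= 1)
  if (!identical(loss, "cross_entropy"))
    stop("unsupported loss: ", loss, call. = FALSE)
  structure(list(lr0 = lr0, momentum = momentum,
                 weight_decay = weight_decay, power = power,
                 max_iter = as.integer(max_iter),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), loss = loss,
                 val_every = val_every),
            class = "train_config")
}

#' Polynomial learning-rate schedule
#'
#' `lr(iter) = lr0 * (1 - iter/max_iter)^power`: exactly `lr0` at
#' iteration 0, exactly 0 at `max_iter`, strictly decreasing in between.
#'
#' @param cfg A [train_config()].
#' @param current_iter Iteration count in `0..max_iter`.
#' @return Learning rate.
#' @export
poly_lr <- function(cfg, current_iter) {
  stopifnot(inherits(cfg, "train_config"))
  if (any(current_iter < 0) || any(current_iter > cfg$max_iter))
    stop("current_iter must lie in [0, max_iter]", call. = FALSE)
  cfg$lr0 * (1 - current_iter / cfg$max_iter)^cfg$power
}

#' Predict a label mask for one image
#'
#' Per-pixel argmax over the class logits; ties are broken toward the
#' lower class index (deterministic).
#'
#' @param net A `toothseg_net`.
#' @param img Grayscale matrix in \[0,1\].
#' @return Integer matrix of class labels, same size as `img`.
#' @export
predict_mask <- function(net, img) {
  logits <- net_forward(net, img)
  d <- dim(logits)
  lm <- logits; dim(lm) <- c(d[1] * d[2], d[3])
  lab <- max.col(lm, ties.method = "first") - 1L
  matrix(as.integer(lab), d[1], d[2])
}

#' Validate a network on a set of image/mask pairs
#'
#' Argmax predictions pooled into one confusion matrix over the whole
#' set, then MPA and MIoU.
#'
#' @param net A `toothseg_net`.
#' @param val_set List of `sample_pair` objects.
#' @param k Number of foreground classes (defaults to
#'   `net$cfg$n_classes - 1`).
#' @return List with `mpa`, `miou`, `per_class`, `confusion`.
#' @export
validate <- function(net, val_set, k = NULL) {
  stopifnot(length(val_set) >= 1)
  if (is.null(k)) k <- net$cfg$n_classes - 1L
  preds <- lapply(val_set, function(sp) predict_mask(net, sp$image))
  truths <- lapply(val_set, `[[`, "mask")
  evaluate_masks(truths, preds, k)
}

#' Train a network with SGD, momentum, weight decay, and poly LR decay
#'
#' Each iteration draws a batch (with replacement when the dataset is
#' smaller than the batch), averages the cross-entropy gradient over the
#' batch, adds the weight-decay term, and takes one momentum-SGD step at
#' the scheduled learning rate:
#' `v <- momentum*v - lr*(grad + weight_decay*w); w <- w + v`.
#' Fully seeded: the same seed, data, and initial weights reproduce the
#' loss history exactly.
#'
#' @param net A `toothseg_net`.
#' @param dataset Non-empty list of `sample_pair` objects (spatial sizes
#'   divisible by the output stride).
#' @param cfg A [train_config()].
#' @param val_set Optional validation pairs for periodic MPA/MIoU.
#' @param verbose Print progress every `verbose` iterations (0 = quiet).
#' @return List with the trained `net` and `history` (data frame of
#'   iteration, loss, lr, and validation metrics where computed).
#' @export
train <- function(net, dataset, cfg, val_set = NULL, verbose = 0L) {
  stopifnot(inherits(net, "toothseg_net"), inherits(cfg, "train_config"),
            length(dataset) >= 1)
  set.seed(cfg$seed)
  vel <- lapply(net$params, function(w) {
    if (is.null(dim(w))) numeric(length(w)) else array(0, dim(w))
  })
  hist <- vector("list", cfg$max_iter)
  for (it in seq_len(cfg$max_iter)) {
    lr <- poly_lr(cfg, it - 1L)
    idx <- sample.int(length(dataset), cfg$batch_size,
                      replace = cfg$batch_size > length(dataset))
    grads <- NULL
    loss_acc <- 0
    for (b in idx) {
      sp <- dataset[[b]]
      fw <- net_forward(net, sp$image, want = "cache")
      ls <- softmax_ce(fw$logits, sp$mask)
      loss_acc <- loss_acc + ls$loss
      gb <- net_backward(net, fw, ls$dlogits)
      grads <- if (is.null(grads)) gb
               else mapply(`+`, grads, gb[names(grads)], SIMPLIFY = FALSE)
    }
    loss <- loss_acc / length(idx)
    if (!is.finite(loss))
      stop("training diverged (non-finite loss) at iteration ", it,
           call. = FALSE)
    for (nm in names(net$params)) {
      gmean <- grads[[nm]] / length(idx)
      vel[[nm]] <- cfg$momentum * vel[[nm]] -
        lr * (gmean + cfg$weight_decay * net$params[[nm]])
      net$params[[nm]] <- net$params[[nm]] + vel[[nm]]
    }
    row <- data.frame(iter = it, loss = loss, lr = lr,
                      val_mpa = NA_real_, val_miou = NA_real_)
    if (!is.null(val_set) && is.finite(cfg$val_every) &&
        it %% cfg$val_every == 0) {
      vm <- validate(net, val_set)
      row$val_mpa <- vm$mpa; row$val_miou <- vm$miou
    }
    hist[[it]] <- row
    if (verbose > 0 && it %% verbose == 0)
      message(sprintf("iter %4d  loss %.4f  lr %.5f", it, loss, lr))
  }
  history <- do.call(rbind, hist)
  if (!is.null(val_set)) {
    vm <- validate(net, val_set)
    attr(history, "final_val") <- vm
  }
  list(net = net, history = history)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
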