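#' Configuration of the calibrated segmentation loss
#'
#' Defaults follow the calibrated training setup: label-smoothing factor
#' 0.2, logit margin 10, two classes (background / aggressive lesion), and
#' equal weighting of the Dice and cross-entropy terms ("a simple average").
#'
#' @param alpha label-smoothing factor in `[0, 1)`.
#' @param margin non-negative logit margin (use `Inf` to disable).
#' @param n_classes number of classes `K >= 2`.
#' @param weights length-2 weights for (Dice, cross-entropy) terms.
#' @return object of class `calibrated_loss_config`.
#' @export
calibrated_loss_config <- function(alpha = 0.2, margin = 10,
                                   n_classes = 2L,
                                   weights = c(0.5, 0.5)) {
  if (alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)")
  if (margin < 0) stop("margin must be >= 0")
  if (n_classes < 2L) stop("need at least 2 classes")
  if (length(weights) != 2L || any(weights < 0)) {
    stop("weights must be 2 non-negative values")
  }
  structure(list(alpha = alpha, margin = margin,
                 n_classes = as.integer(n_classes), weights = weights),
            class = "calibrated_loss_config")
}

#' Label smoothing
#'
#' `y' = y * (1 - alpha) + alpha / K`: each one-hot row is pulled toward
#' the uniform distribution, leaving a valid distribution (rows sum to 1).
#'
#' @param targets numeric matrix, rows = voxels, columns = `K` one-hot
#'   class indicators.
#' @param alpha smoothing factor in `[0, 1)`.
#' @return matrix of smoothed target distributions.
#' @export
smooth_labels <- function(targets, alpha = 0.2) {
  targets <- as.matrix(targets)
  if (alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)")
  if (!all(targets %in% c(0, 1)) ||
      any(abs(rowSums(targets) - 1) > 1e-12)) {
    stop("targets must be one-hot rows")
  }
  targets * (1 - alpha) + alpha / ncol(targets)
}

#' Margin penalty on logit gaps
#'
#' Hinge penalty on pairwise logit gaps exceeding the margin: the mean over
#' voxels and classes of `max(0, (max_logit - logit_k) - m)`. Zero whenever
#' every gap is at most `m`; shrinks as `m` grows. Constraining logit gaps
#' keeps the softmax from saturating, which is what calibrates the
#' predicted probabilities.
#'
#' @param logits numeric matrix, rows = voxels, columns = classes.
#' @param margin non-negative margin `m` (`Inf` disables the penalty).
#' @return non-negative scalar.
#' @export
margin_penalty <- function(logits, margin = 10) {
  logits <- as.matrix(logits)
  if (margin < 0) stop("margin must be >= 0")
  if (!is.finite(margin)) return(0)
  gaps <- apply(logits, 1, max) - logits
  mean(pmax(0, gaps - margin))
}

row_softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# soft Dice loss averaged over foreground channels (k >= 2)
soft_dice_loss <- function(p, g, eps = 1e-5) {
  fg <- seq.int(2L, ncol(p))
  losses <- vapply(fg, function(k) {
    1 - (2 * sum(p[, k] * g[, k]) + eps) / (sum(p[, k]) + sum(g[, k]) + eps)
  }, numeric(1))
  mean(losses)
}

#' Calibrated segmentation loss
#'
#' Weighted sum (default: simple average) of the soft Dice loss and the
#' cross-entropy against label-smoothed targets, plus the margin penalty:
#' `w1 * Dice + w2 * CE(smoothed) + margin_penalty`. With `alpha = 0` and
#' `margin = Inf` this reduces exactly to the plain average of Dice and
#' cross-entropy losses.
#'
#' @param logits numeric matrix, rows = voxels, columns = `K` classes.
#' @param targets one-hot matrix of the same shape.
#' @param cfg a [calibrated_loss_config()].
#' @return finite scalar loss.
#' @export
calibrated_loss <- function(logits, targets,
                            cfg = calibrated_loss_config()) {
  logits <- as.matrix(logits); targets <- as.matrix(targets)
  if (!identical(dim(logits), dim(targets))) {
    stop("logits and targets must have identical shapes")
  }
  if (ncol(logits) != cfg$n_classes) {
    stop("number of columns must equal cfg$n_classes")
  }
  p <- row_softmax(logits)
  y <- smooth_labels(targets, cfg$alpha)
  ce <- -mean(rowSums(y * log(pmax(p, 1e-12))))
  dl <- soft_dice_loss(p, targets)
  cfg$weights[1] * dl + cfg$weights[2] * ce +
    margin_penalty(logits, cfg$margin)
}

#' Polynomial learning-rate decay
#'
#' `base_lr * (1 - epoch / epoch_max)^power` — the schedule that anneals
#' the learning rate from `base_lr` at epoch 0 to 0 at `epoch_max`.
#'
#' @param epoch current epoch, `0 <= epoch <= epoch_max`.
#' @param epoch_max final epoch (> 0).
#' @param base_lr initial learning rate, default 0.001.
#' @param power decay exponent, default 0.9.
#' @return learning rate(s).
#' @export
poly_lr <- function(epoch, epoch_max, base_lr = 0.001, power = 0.9) {
  if (epoch_max <= 0) stop("epoch_max must be positive")
  if (any(epoch < 0) || any(epoch > epoch_max)) {
    stop("epoch must lie in [0, epoch_max]")
  }
  base_lr * (1 - epoch / epoch_max)^power
}
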