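#' Loss configuration
#'
#' @param rampup_epochs epochs over which the unsupervised weight ramps up
#'   (>= 1).
#' @param w_max plateau value of the unsupervised weight (> 0).
#' @param smooth soft-Dice smoothing constant keeping empty masks
#'   well-defined.
#' @return A `loss_config` list.
#' @export
loss_config <- function(rampup_epochs = 10, w_max = 1.0, smooth = 1e-6) {
  stopifnot_config(rampup_epochs >= 1, "rampup_epochs must be >= 1")
  stopifnot_config(w_max > 0, "w_max must be > 0")
  structure(list(rampup_epochs = rampup_epochs, w_max = w_max, smooth = smooth),
            class = "loss_config")
}

# Soft multi-class Dice loss (1 - mean DSC) and its gradient w.r.t.
# probabilities. Classes absent from both y and the prediction argmax are
# skipped so that irrelevant classes do not dilute the average.
soft_dice_parts <- function(p, y_onehot, smooth, want_grad = FALSE) {
  inter <- colSums(p * y_onehot)
  psum <- colSums(p)
  gsum <- colSums(y_onehot)
  pred_cls <- max.col(p, ties.method = "first")
  present <- which(gsum > 0 | tabulate(pred_cls, ncol(p)) > 0)
  num <- 2 * inter + smooth
  den <- psum + gsum + smooth
  dsc <- num / den
  loss <- 1 - mean(dsc[present])
  if (!want_grad) return(list(loss = loss))
  dp <- matrix(0, nrow(p), ncol(p))
  scale <- -1 / length(present)
  for (c in present)
    dp[, c] <- scale * (2 * y_onehot[, c] / den[c] - num[c] / den[c]^2)
  list(loss = loss, dp = dp)
}

# Cross-entropy + soft Dice for one image with optional gradient w.r.t.
# logits. p-rows are softmax distributions; y is 0-based class ids.
sup_loss_one <- function(logits, y, smooth = 1e-6, want_grad = FALSE) {
  d <- dim(logits)
  L <- d[3]
  yv <- as.integer(y)
  if (any(yv < 0 | yv >= L)) stop("label out of range", call. = FALSE)
  z <- logits_to_mat(logits)
  p <- softmax_rows(z)
  n <- nrow(p)
  idx <- cbind(seq_len(n), yv + 1L)
  ce <- -mean(log(pmax(p[idx], 1e-12)))
  y1 <- matrix(0, n, L)
  y1[idx] <- 1
  dice <- soft_dice_parts(p, y1, smooth, want_grad)
  loss <- dice$loss + ce
  if (!want_grad) return(list(loss = loss))
  # CE grad wrt logits: (p - y)/n ; Dice grad via softmax Jacobian
  dz_ce <- (p - y1) / n
  gdot <- rowSums(dice$dp * p)
  dz_dice <- p * (dice$dp - gdot)
  list(loss = loss, dlogits = mat_to_logits(dz_ce + dz_dice, d[1], d[2]))
}

#' Supervised segmentation loss (soft Dice + cross-entropy)
#'
#' For each labelled image the loss is `(1 - DSC) + mean_i CE_i`, where DSC is
#' the soft Dice coefficient computed from softmax probabilities and averaged
#' over the classes present in the ground truth or the prediction, and the
#' cross-entropy is averaged over pixels. A batch (list input) is averaged
#' over images.
#'
#' @param logits H x W x L logit array, or list of such arrays.
#' @param y H x W integer label mask (values in 0..L-1), or list of masks.
#' @param smooth Dice smoothing constant.
#' @return Scalar loss.
#' @export
supervised_loss <- function(logits, y, smooth = 1e-6) {
  if (is.list(logits)) {
    return(mean(mapply(function(l, m) sup_loss_one(l, m, smooth)$loss,
                       logits, y)))
  }
  sup_loss_one(logits, y, smooth)$loss
}

# Soft cross-entropy over confident pixels for one image; returns loss and
# gradient w.r.t. strong-branch logits. Exactly 0 (and zero gradient) when
# the confident set is empty.
unsup_loss_one <- function(pseudo, logits_s, want_grad = FALSE) {
  d <- dim(logits_s)
  conf <- as.vector(pseudo$confident)
  nconf <- sum(conf)
  if (nconf == 0) {
    out <- list(loss = 0)
    if (want_grad) out$dlogits <- array(0, d)
    return(out)
  }
  z <- logits_to_mat(logits_s)
  p <- softmax_rows(z)
  tg <- logits_to_mat(pseudo$targets)
  ce <- -rowSums(tg * log(pmax(p, 1e-12)))
  loss <- sum(ce[conf]) / nconf
  if (!want_grad) return(list(loss = loss))
  dz <- (p - tg) * (conf / nconf)
  list(loss = loss, dlogits = mat_to_logits(dz, d[1], d[2]))
}

#' Confidence-masked unsupervised consistency loss
#'
#' Mean over confident pixels of the soft cross-entropy between the sharpened
#' pseudo-label distribution and the strong-branch probability, i.e.
#' `-sum_c ytilde_i^c log p_i^c`. Returns exactly 0 when the confident set is
#' empty. A batch (list input) is averaged over unlabelled images.
#'
#' @param pseudo a `pseudo_label` (or list of them).
#' @param probs_strong H x W x L probability array from the strong branch (or
#'   list of them).
#' @return Scalar loss.
#' @export
unsupervised_loss <- function(pseudo, probs_strong) {
  one <- function(pl, pr) {
    conf <- as.vector(pl$confident)
    nconf <- sum(conf)
    if (nconf == 0) return(0)
    p <- logits_to_mat(pr)
    tg <- logits_to_mat(pl$targets)
    ce <- -rowSums(tg * log(pmax(p, 1e-12)))
    sum(ce[conf]) / nconf
  }
  if (is.list(pseudo) && !inherits(pseudo, "pseudo_label"))
    return(mean(mapply(one, pseudo, probs_strong)))
  one(pseudo, probs_strong)
}

#' Gaussian ramp-up weight for the unsupervised loss
#'
#' `w(0) = 0`; for `0 < epoch < rampup_epochs`,
#' `w = w_max * exp(-5 * (1 - epoch / rampup_epochs)^2)`; from
#' `rampup_epochs` onward `w = w_max`. Monotone non-decreasing, so the
#' supervised loss dominates early training and the consistency term phases
#' in smoothly.
#'
#' @param epoch current epoch (0-based, >= 0).
#' @param cfg a [loss_config()].
#' @return Scalar weight.
#' @export
rampup_weight <- function(epoch, cfg) {
  if (epoch <= 0) return(0)
  if (epoch >= cfg$rampup_epochs) return(cfg$w_max)
  cfg$w_max * exp(-5 * (1 - epoch / cfg$rampup_epochs)^2)
}

#' Total training loss
#'
#' `L = L_s + w(epoch) * L_u` with the Gaussian ramp-up weight.
#'
#' @param L_s supervised loss value.
#' @param L_u unsupervised loss value.
#' @param epoch current epoch (0-based).
#' @param cfg a [loss_config()].
#' @return Scalar total loss.
#' @export
total_loss <- function(L_s, L_u, epoch, cfg) {
  L_s + rampup_weight(epoch, cfg) * L_u
}
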