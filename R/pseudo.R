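#' Temperature sharpening of a probability distribution
#'
#' Raises each probability to the power `1/T` and renormalizes:
#' `sharpen(d, T)_i = d_i^{1/T} / sum_j d_j^{1/T}`. Temperatures below one
#' concentrate mass on the argmax; `T = 1` is the identity; as `T -> 0` the
#' result approaches the one-hot argmax.
#'
#' @param d numeric probability vector (simplex), or a matrix whose rows are
#'   distributions.
#' @param temperature positive temperature `T`.
#' @return Sharpened distribution(s), same shape as `d`.
#' @export
sharpen <- function(d, temperature) {
  stopifnot_config(temperature > 0, "temperature must be > 0")
  vec <- !is.matrix(d)
  m <- if (vec) matrix(d, 1) else d
  if (any(rowSums(m) == 0))
    stop("zero probability vector cannot be sharpened", call. = FALSE)
  if (temperature == 1) return(d)   # exponent 1: exact identity
  # log-space for numerical stability at small T (d^(1/T) underflows)
  lg <- log(m) / temperature
  lg <- lg - apply(lg, 1, max)
  p <- exp(lg)
  p <- p / rowSums(p)
  if (vec) as.vector(p) else p
}

#' Build a pseudo-label from weak-branch logits
#'
#' Applies a per-pixel softmax, records the confident set as the pixels whose
#' pre-sharpening softmax maximum reaches the threshold `t` (intersected with
#' the validity mask from the weak-transform inversion), and sharpens the
#' softmax with temperature `T` to form the soft targets. The confident set is
#' deliberately computed from the unsharpened probabilities: sharpening
#' inflates the maximum, so thresholding after it would loosen the filter.
#' No gradient information is retained; pseudo-labels are constants
#' downstream.
#'
#' @param logits_w H x W x L array of weak-branch logits mapped back to the
#'   original frame.
#' @param validity H x W logical validity mask (default all valid).
#' @param temperature sharpening temperature `T` (> 0); default 0.5.
#' @param threshold confidence threshold `t` in [0, 1]; default 0.8.
#' @return A `pseudo_label`: list with `targets` (H x W x L sharpened
#'   distributions), `confident` (H x W logical), `threshold`, `temperature`.
#' @export
make_pseudo_label <- function(logits_w, validity = NULL, temperature = 0.5,
                              threshold = 0.8) {
  stopifnot_config(threshold >= 0 && threshold <= 1,
                   "threshold must lie in [0, 1]")
  d <- dim(logits_w)
  if (is.null(validity)) validity <- matrix(TRUE, d[1], d[2])
  p <- softmax_rows(logits_to_mat(logits_w))
  conf <- matrix(apply(p, 1, max) >= threshold, d[1], d[2]) & validity
  targets <- mat_to_logits(sharpen(p, temperature), d[1], d[2])
  structure(list(targets = targets, confident = conf,
                 threshold = threshold, temperature = temperature),
            class = "pseudo_label")
}
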