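#' Adversarial augmentation configuration
#'
#' @param epsilon L-infinity perturbation budget in [0,1] intensity units
#'   (default 0.08, the value found optimal in the reference experiments).
#' @param steps number of gradient-sign iterations K (default 25; desk-scale
#'   profiles use 3).
#' @param enabled logical; `FALSE` disables the attack (hand-crafted
#'   augmentations only).
#' @return An `adv_config` list.
#' @export
adv_config <- function(epsilon = 0.08, steps = 25, enabled = TRUE) {
  stopifnot_config(epsilon >= 0, "epsilon must be >= 0")
  stopifnot_config(steps >= 1, "steps must be >= 1")
  structure(list(epsilon = epsilon, steps = as.integer(steps),
                 enabled = isTRUE(enabled)), class = "adv_config")
}

#' Project an image into the epsilon-neighbourhood of a reference image
#'
#' Per-pixel clipping to `[x0 - epsilon, x0 + epsilon]` intersected with the
#' valid image range [0,1]. Pixels already satisfying both constraints pass
#' through unchanged.
#'
#' @param x candidate image array.
#' @param x0 reference image array, same shape.
#' @param epsilon L-infinity budget (>= 0).
#' @return Clipped image array.
#' @export
clip_neighbourhood <- function(x, x0, epsilon) {
  if (!identical(dim(x), dim(x0)))
    stop("shape mismatch between x and x0", call. = FALSE)
  clamp01(pmin(pmax(x, x0 - epsilon), x0 + epsilon))
}

sign0 <- function(x) sign(x)  # sign(0) = 0: zero gradient leaves the pixel

#' Iterative FGSM refinement of a strongly-augmented image
#'
#' Runs K iterations of
#' `x_{k+1} = Clip_{x0,eps}(x_k + (eps/K) * sign(grad_x L_u(f(x_k), ytilde)))`
#' against the frozen model, with the pseudo-label held constant. The attack
#' maximises the same confidence-masked consistency loss that training
#' minimises, so the strong branch is always presented with the hardest
#' admissible version of its input. Model parameters are never touched; an
#' empty confident set yields a zero attack gradient and returns `x0`.
#'
#' @param model a model object implementing [forward()] and
#'   [input_gradient()].
#' @param x0 H x W x C initial strongly-augmented image in [0,1].
#' @param pseudo a `pseudo_label` for the same geometry.
#' @param cfg an [adv_config()].
#' @return The attacked image, within `epsilon` of `x0` and inside [0,1].
#' @export
ifgsm_attack <- function(model, x0, pseudo, cfg) {
  if (!inherits(cfg, "adv_config")) cfg <- do.call(adv_config, cfg)
  if (cfg$epsilon == 0) return(clamp01(x0))
  if (sum(pseudo$confident) == 0) return(x0)
  step <- cfg$epsilon / cfg$steps
  xk <- clamp01(x0)
  for (k in seq_len(cfg$steps)) {
    logits <- forward(model, xk)
    g <- unsup_loss_one(pseudo, logits, want_grad = TRUE)
    dx <- input_gradient(model, xk, g$dlogits)
    xk <- clip_neighbourhood(xk + step * sign0(dx), x0, cfg$epsilon)
  }
  xk
}

#' Single-step FGSM attack
#'
#' Equivalent to [ifgsm_attack()] with `steps = 1`: one signed gradient step
#' of size `epsilon` followed by the neighbourhood projection.
#'
#' @inheritParams ifgsm_attack
#' @param epsilon L-infinity budget.
#' @return The attacked image.
#' @export
fgsm_attack <- function(model, x0, pseudo, epsilon) {
  ifgsm_attack(model, x0, pseudo, adv_config(epsilon = epsilon, steps = 1))
}
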