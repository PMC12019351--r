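#' Training configuration
#'
#' Defaults follow the reference full-scale recipe: SGD with momentum 0.95,
#' initial learning rate 1e-2 decayed per epoch by
#' `lr_ini * (1 - epoch/epochs) * eta` with `eta = 0.7`, batches mixing equal
#' numbers of labelled and unlabelled images, adversarial refinement with
#' `epsilon = 0.08`, `K = 25`. Desk-scale profiles shrink epochs, batch size
#' and K (see [desk_profile()]).
#'
#' @param epochs number of training epochs.
#' @param batch_size images per pathway per step.
#' @param lr_ini initial learning rate.
#' @param eta learning-rate decay factor in (0, 1].
#' @param momentum SGD momentum in [0, 1).
#' @param seed integer seed controlling all training randomness.
#' @param temperature pseudo-label sharpening temperature T.
#' @param threshold pseudo-label confidence threshold t.
#' @param adversarial an [adv_config()].
#' @param loss a [loss_config()].
#' @param weak_enabled logical; `FALSE` replaces the weak transform by the
#'   identity (ablation).
#' @param strong_enabled logical; `FALSE` feeds the original image to the
#'   strong branch (ablation).
#' @param weak_kinds transform kinds for the weak branch.
#' @param strong_ranges magnitude ranges for the strong ops.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 1000, batch_size = 64, lr_ini = 0.01,
                         eta = 0.7, momentum = 0.95, seed = 1,
                         temperature = 0.5, threshold = 0.8,
                         adversarial = adv_config(),
                         loss = loss_config(rampup_epochs = max(1, round(0.3 * epochs))),
                         weak_enabled = TRUE, strong_enabled = TRUE,
                         weak_kinds = WEAK_KINDS,
                         strong_ranges = default_strong_ranges()) {
  stopifnot_config(batch_size >= 1, "batch_size must be >= 1")
  stopifnot_config(eta > 0 && eta <= 1, "eta must lie in (0, 1]")
  stopifnot_config(momentum >= 0 && momentum < 1, "momentum must lie in [0, 1)")
  if (!inherits(adversarial, "adv_config"))
    adversarial <- do.call(adv_config, adversarial)
  if (!inherits(loss, "loss_config")) loss <- do.call(loss_config, loss)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr_ini = lr_ini, eta = eta, momentum = momentum,
                 seed = as.integer(seed), temperature = temperature,
                 threshold = threshold, adversarial = adversarial, loss = loss,
                 weak_enabled = isTRUE(weak_enabled),
                 strong_enabled = isTRUE(strong_enabled),
                 weak_kinds = weak_kinds, strong_ranges = strong_ranges),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' `lr = lr_ini * (1 - epoch / epochs) * eta`: linear decay to zero scaled by
#' the constant factor `eta`.
#'
#' @param epoch epoch index in `0..epochs`.
#' @param cfg a [train_config()].
#' @return Learning rate.
#' @export
lr_schedule <- function(epoch, cfg) {
  cfg$lr_ini * (1 - epoch / cfg$epochs) * cfg$eta
}

#' Sample one mixed batch
#'
#' Draws `batch_size` labelled pairs and `batch_size` unlabelled images from
#' the dataset (with replacement when a pool is smaller than the batch).
#' Returns an empty unlabelled batch when the unlabelled pool is empty
#' (supervised-only mode).
#'
#' @param dataset a `seg_dataset`.
#' @param batch_size images per pathway.
#' @return `list(labelled, unlabelled)`.
#' @export
make_mixed_batch <- function(dataset, batch_size) {
  n_lab <- length(dataset$labelled)
  stopifnot_config(n_lab >= 1, "labelled set is empty")
  li <- sample(n_lab, batch_size, replace = batch_size > n_lab)
  n_unl <- length(dataset$unlabelled)
  ui <- if (n_unl == 0) integer(0) else
    sample(n_unl, batch_size, replace = batch_size > n_unl)
  list(labelled = dataset$labelled[li], unlabelled = dataset$unlabelled[ui])
}

stack_images <- function(imgs) {
  d <- dim(imgs[[1]])
  array(unlist(imgs), c(d, length(imgs)))
}

zero_like <- function(params) {
  lapply(params, function(a) if (is.null(dim(a))) numeric(length(a))
         else array(0, dim(a)))
}

sgd_update <- function(model, opt, grads, lr, momentum) {
  for (nm in names(model$params)) {
    opt[[nm]] <- momentum * opt[[nm]] + grads[[nm]]
    model$params[[nm]] <- model$params[[nm]] - lr * opt[[nm]]
  }
  list(model = model, opt = opt)
}

# Batched I-FGSM: attacks every unlabelled image in one forward/backward per
# iteration. Instance normalization is per-sample, so the batched gradients
# equal the per-image gradients.
ifgsm_attack_batch <- function(model, X0, pseudos, cfg) {
  nb <- dim(X0)[4]
  if (cfg$epsilon == 0 || !any(vapply(pseudos, function(p) any(p$confident),
                                      logical(1))))
    return(clamp01(X0))
  step <- cfg$epsilon / cfg$steps
  Xk <- clamp01(X0)
  for (k in seq_len(cfg$steps)) {
    fc <- model_forward(model, Xk, want_cache = TRUE)
    dl <- array(0, dim(fc$logits))
    for (i in seq_len(nb)) {
      g <- unsup_loss_one(pseudos[[i]],
                          array(fc$logits[, , , i], dim(fc$logits)[1:3]),
                          want_grad = TRUE)
      dl[, , , i] <- g$dlogits
    }
    dx <- model_backward(model, fc$caches, dl)$dx
    Xk <- clip_neighbourhood(Xk + step * sign0(dx), X0, cfg$epsilon)
  }
  Xk
}

#' One training step
#'
#' Executes, in order: (1) supervised forward and Dice+CE loss on the
#' labelled batch; (2) weak branch: per-image invertible spatial transform,
#' forward pass, inversion onto the original frame and pseudo-label
#' extraction (no gradients retained); (3) strong branch: photometric
#' initialization followed by batched I-FGSM refinement against the frozen
#' current parameters; (4) forward pass on the attacked images and the
#' confidence-masked consistency loss; (5) a single SGD-momentum update on
#' `L_s + w(epoch) L_u`. Both branches and the supervised pathway share one
#' parameter set. The unsupervised pathway is skipped whenever
#' `w(epoch) == 0` (it could not affect the update).
#'
#' @param model a `segmatch_model`.
#' @param opt optimizer state (named velocity list) or `NULL` to initialise.
#' @param batch a mixed batch from [make_mixed_batch()].
#' @param cfg a [train_config()].
#' @param epoch current 0-based epoch (drives ramp-up and learning rate).
#' @return List with updated `model`, `opt`, and a `report` holding `L_s`,
#'   `L_u`, `w`, `attack_norm`, `conf_frac`.
#' @export
train_step <- function(model, opt, batch, cfg, epoch) {
  if (is.null(opt)) opt <- zero_like(model$params)
  lr <- lr_schedule(epoch, cfg)
  w <- rampup_weight(epoch, cfg$loss)
  nb <- length(batch$labelled)

  X <- stack_images(lapply(batch$labelled, `[[`, "image"))
  fc <- model_forward(model, X, want_cache = TRUE, training = TRUE)
  model$stats <- fc$stats
  dl <- array(0, dim(fc$logits))
  L_s <- 0
  for (i in seq_len(nb)) {
    r <- sup_loss_one(array(fc$logits[, , , i], dim(fc$logits)[1:3]),
                      batch$labelled[[i]]$mask, cfg$loss$smooth,
                      want_grad = TRUE)
    L_s <- L_s + r$loss / nb
    dl[, , , i] <- r$dlogits / nb
  }
  if (!is.finite(L_s)) stop("non-finite supervised loss", call. = FALSE)
  grads <- model_backward(model, fc$caches, dl)$grads

  L_u <- 0; attack_norm <- 0; conf_frac <- NA_real_
  nu <- length(batch$unlabelled)
  if (nu > 0 && w > 0) {
    hw <- dim(batch$unlabelled[[1]])[1:2]
    pseudos <- vector("list", nu)
    Xw <- vector("list", nu); tfs <- vector("list", nu)
    for (i in seq_len(nu)) {
      tfs[[i]] <- if (cfg$weak_enabled)
        sample_weak_transform(hw, cfg$weak_kinds) else weak_transform("identity")
      Xw[[i]] <- apply_weak(tfs[[i]], batch$unlabelled[[i]])
    }
    # batch statistics (training-mode normalization) without committing a
    # running-statistics update: the pseudo-label pass is read-only
    logits_w <- model_forward(model, stack_images(Xw), training = TRUE)$logits
    for (i in seq_len(nu)) {
      inv <- invert_on_logits(tfs[[i]], array(logits_w[, , , i],
                                              dim(logits_w)[1:3]), hw)
      pseudos[[i]] <- make_pseudo_label(inv$logits, inv$valid,
                                        cfg$temperature, cfg$threshold)
    }
    conf_frac <- mean(vapply(pseudos, function(p) mean(p$confident),
                             numeric(1)))

    Xs0 <- lapply(seq_len(nu), function(i) {
      if (cfg$strong_enabled)
        apply_strong_init(sample_strong_augmentation(cfg$strong_ranges),
                          batch$unlabelled[[i]])
      else batch$unlabelled[[i]]
    })
    X0 <- stack_images(Xs0)
    Xs <- if (cfg$adversarial$enabled)
      ifgsm_attack_batch(model, X0, pseudos, cfg$adversarial) else X0
    attack_norm <- max(abs(Xs - X0))

    fs <- model_forward(model, Xs, want_cache = TRUE, training = TRUE)
    model$stats <- fs$stats
    dls <- array(0, dim(fs$logits))
    for (i in seq_len(nu)) {
      g <- unsup_loss_one(pseudos[[i]], array(fs$logits[, , , i],
                                              dim(fs$logits)[1:3]),
                          want_grad = TRUE)
      L_u <- L_u + g$loss / nu
      dls[, , , i] <- g$dlogits * (w / nu)
    }
    if (!is.finite(L_u)) stop("non-finite unsupervised loss", call. = FALSE)
    ugrads <- model_backward(model, fs$caches, dls)$grads
    for (nm in names(grads)) grads[[nm]] <- grads[[nm]] + ugrads[[nm]]
  }

  upd <- sgd_update(model, opt, grads, lr, cfg$momentum)
  list(model = upd$model, opt = upd$opt,
       report = list(L_s = L_s, L_u = L_u, w = w, attack_norm = attack_norm,
                     conf_frac = conf_frac))
}

#' Train a model with semi-supervised consistency
#'
#' Runs `epochs` passes over the unlabelled pool (the labelled pool cycles
#' with per-epoch reshuffles; with no unlabelled data the loop degenerates to
#' the plain supervised trainer over the labelled pool). Deterministic under
#' `cfg$seed`.
#'
#' @param dataset a `seg_dataset`.
#' @param cfg a [train_config()].
#' @param model_cfg a [model_config()]; defaults to a depth-2 model matching
#'   the dataset's class count.
#' @param val_set optional list of `list(image, mask)` pairs evaluated each
#'   epoch.
#' @return List with `model`, `history` (one row per epoch: epoch, lr, L_s,
#'   L_u, w, attack_norm, conf_frac, val_dice).
#' @export
train <- function(dataset, cfg, model_cfg = NULL, val_set = NULL) {
  if (is.null(model_cfg))
    model_cfg <- model_config(n_classes = dataset$n_classes, seed = cfg$seed)
  model <- build_model(model_cfg)
  opt <- zero_like(model$params)
  hist <- list()
  n_lab <- length(dataset$labelled)
  n_unl <- length(dataset$unlabelled)
  stopifnot_config(n_lab >= 1, "labelled set is empty")
  bs <- cfg$batch_size
  with_seed(derive_seed(cfg$seed, 0L, salt = 47L), {
    for (epoch in seq_len(cfg$epochs) - 1L) {
      pool <- max(n_unl, n_lab)
      steps <- ceiling(pool / bs)
      lab_order <- rep(sample(n_lab), length.out = steps * bs)
      unl_order <- if (n_unl > 0) rep(sample(n_unl), length.out = steps * bs)
        else integer(0)
      rep_sum <- c(L_s = 0, L_u = 0, attack_norm = 0)
      conf <- numeric(0)
      for (s in seq_len(steps)) {
        take <- ((s - 1) * bs + 1):(s * bs)
        batch <- list(labelled = dataset$labelled[lab_order[take]],
                      unlabelled = if (n_unl > 0)
                        dataset$unlabelled[unl_order[take]] else list())
        st <- train_step(model, opt, batch, cfg, epoch)
        model <- st$model; opt <- st$opt
        rep_sum <- rep_sum + c(st$report$L_s, st$report$L_u,
                               st$report$attack_norm)
        if (!is.na(st$report$conf_frac)) conf <- c(conf, st$report$conf_frac)
      }
      val_dice <- if (!is.null(val_set))
        evaluate(model, val_set, dataset$n_classes)$dice else NA_real_
      hist[[epoch + 1]] <- data.frame(
        epoch = epoch, lr = lr_schedule(epoch, cfg),
        L_s = rep_sum[["L_s"]] / steps, L_u = rep_sum[["L_u"]] / steps,
        w = rampup_weight(epoch, cfg$loss),
        attack_norm = rep_sum[["attack_norm"]] / steps,
        conf_frac = if (length(conf)) mean(conf) else NA_real_,
        val_dice = val_dice)
    }
  })
  history <- if (length(hist)) do.call(rbind, hist) else
    data.frame(epoch = integer(0), lr = numeric(0), L_s = numeric(0),
               L_u = numeric(0), w = numeric(0), attack_norm = numeric(0),
               conf_frac = numeric(0), val_dice = numeric(0))
  list(model = model, history = history)
}

#' Run the augmentation ablation grid
#'
#' Trains four variants on the same dataset and seed: the full method,
#' no-adversarial (hand-crafted strong augmentation only), no-weak
#' (additionally replacing the weak transform with the identity), and
#' no-strong (additionally feeding the original image to the strong branch;
#' pseudo-labelling alone). Returns the held-out metric report per variant.
#'
#' @param dataset a `seg_dataset`.
#' @param cfg a [train_config()] for the full variant.
#' @param test_set labelled evaluation pairs.
#' @param model_cfg optional [model_config()].
#' @param variants subset of
#'   `c("full", "no_adversarial", "no_weak", "no_strong")`.
#' @return Named list of `list(report, history)` per variant.
#' @export
ablate <- function(dataset, cfg, test_set, model_cfg = NULL,
                   variants = c("full", "no_adversarial", "no_weak",
                                "no_strong")) {
  out <- list()
  for (v in variants) {
    vcfg <- cfg
    if (v != "full") vcfg$adversarial$enabled <- FALSE
    if (v == "no_weak") vcfg$weak_enabled <- FALSE
    if (v == "no_strong") vcfg$strong_enabled <- FALSE
    fit <- train(dataset, vcfg, model_cfg)
    out[[v]] <- list(report = evaluate(fit$model, test_set,
                                       dataset$n_classes),
                     history = fit$history)
  }
  out
}
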