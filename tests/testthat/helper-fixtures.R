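# Shared fixtures: everything is built in code, nothing is read from disk.

tiny_scene_config <- function(seed = 1, n_classes = 2, hw = 32) {
  scene_config(height = hw, width = hw, n_classes = n_classes,
               object_width_range = c(3, 6), background_texture_scale = 8,
               noise_sd = 0.05, seed = seed)
}

tiny_model <- function(n_classes = 2, seed = 1, base = 4) {
  build_model(model_config(depth = 2, base_channels = base,
                           n_classes = n_classes, seed = seed))
}

random_simplex <- function(n, L) {
  m <- matrix(stats::rexp(n * L), n, L)
  m / rowSums(m)
}

# Frozen linear per-pixel softmax classifier: logits[h,w,] = x[h,w,] %*% W + b.
# Used as an analytically tractable oracle for the gradient-sign attacks.
linear_pixel_model <- function(W, b) {
  structure(list(W = W, b = b), class = "linear_model")
}

forward.linear_model <- function(model, x, ...) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  z <- xm %*% model$W + matrix(model$b, d[1] * d[2], length(model$b),
                               byrow = TRUE)
  array(z, c(d[1], d[2], length(model$b)))
}

input_gradient.linear_model <- function(model, x, dlogits, ...) {
  d <- dim(x)
  dz <- matrix(dlogits, d[1] * d[2], ncol(model$W))
  array(dz %*% t(model$W), d)
}

registerS3method("forward", "linear_model", forward.linear_model,
                 envir = asNamespace("segmatch"))
registerS3method("input_gradient", "linear_model", input_gradient.linear_model,
                 envir = asNamespace("segmatch"))

# Brute-force NSD oracle: all-pairs pixel-centre distances, no shared code
# with nsd_score beyond the boundary definition written out longhand.
oracle_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- NULL
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (mask[i, j] == 0) next
    nb <- c(if (i > 1) mask[i - 1, j] else 0L,
            if (i < h) mask[i + 1, j] else 0L,
            if (j > 1) mask[i, j - 1] else 0L,
            if (j < w) mask[i, j + 1] else 0L)
    if (any(nb == 0)) out <- rbind(out, c(i, j))
  }
  out
}

oracle_nsd <- function(pred, gt, tau) {
  bp <- oracle_boundary(pred)
  bg <- oracle_boundary(gt)
  if (is.null(bp) && is.null(bg)) return(1)
  if (is.null(bp) || is.null(bg)) return(0)
  mind <- function(a, B) min(sqrt((a[1] - B[, 1])^2 + (a[2] - B[, 2])^2))
  hp <- sum(apply(bp, 1, mind, B = bg) <= tau)
  hg <- sum(apply(bg, 1, mind, B = bp) <= tau)
  (hp + hg) / (nrow(bp) + nrow(bg))
}

# A model-shaped object that returns one-hot logits for a stored mask
# (oracle predictor used by the evaluate() tests).
oracle_model <- function(mask, n_classes) {
  structure(list(mask = mask, L = n_classes), class = "oracle_model")
}

forward.oracle_model <- function(model, x, ...) {
  h <- nrow(model$mask); w <- ncol(model$mask)
  z <- array(0, c(h, w, model$L))
  for (c in seq_len(model$L) - 1L) z[, , c + 1][model$mask == c] <- 10
  z
}

registerS3method("forward", "oracle_model", forward.oracle_model,
                 envir = asNamespace("segmatch"))

# Reduced-scale profile shared by the behavioural acceptance tests
# (criteria on semi-supervised gain and ablation ordering). The reference
# desk profile (64x64, 200 scenes, 30 epochs) exceeds the CPU test budget,
# so these tests run a proportionally shrunk world: 32x32 scenes, 80 scenes,
# 10% labelled, 15 epochs, K = 3, with the supervised baseline given the
# same optimizer-step budget.
accept_world <- function(seed) {
  sc <- tiny_scene_config(seed = seed)
  ds <- generate_dataset(sc, 80, 0.1)
  test_sc <- sc
  test_sc$seed <- segmatch:::derive_seed(sc$seed, 2L, salt = 53L)
  test <- lapply(seq_len(30), function(i) generate_scene(test_sc, i))
  list(ds = ds, test = test,
       mc = model_config(depth = 2, base_channels = 8, n_classes = 2,
                         seed = seed))
}

accept_train_config <- function(seed, epochs = 30) {
  train_config(epochs = epochs, batch_size = 8, seed = seed,
               adversarial = adv_config(epsilon = 0.08, steps = 3),
               loss = loss_config(rampup_epochs = max(1, round(0.3 * epochs))))
}
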