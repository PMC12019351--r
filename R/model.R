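#' Segmentation backbone configuration
#'
#' A compact residual encoder-decoder in the U-Net style: the encoder stacks
#' stride-2 downsampling convolutions each followed by a residual block; the
#' decoder mirrors it with nearest-neighbour upsampling, 3x3
#' convolution-normalization-ReLU sequences and additive skip connections; a
#' final 1x1 projection produces one logit per class. Normalization is batch
#' normalization: batch statistics (with a running-statistics update) in
#' training mode, running statistics in evaluation and attack passes, so
#' per-image gradients stay independent during the adversarial refinement.
#' All gradients are hand-written and verified against finite differences in
#' the test-suite.
#'
#' @param depth number of down/up levels (>= 1). The reference architecture
#'   uses 6; desk-scale experiments use 2.
#' @param base_channels channel width at full resolution; doubles per level.
#' @param n_classes number of output classes L (>= 2).
#' @param seed integer seed for reproducible parameter initialization.
#' @return A `model_config` list.
#' @export
model_config <- function(depth = 2, base_channels = 8, n_classes = 2, seed = 1) {
  stopifnot_config(depth >= 1, "depth must be >= 1")
  stopifnot_config(n_classes >= 2, "n_classes must be >= 2")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 n_classes = as.integer(n_classes), seed = as.integer(seed)),
            class = "model_config")
}

he_init <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

# Parameter block for one conv + batch-norm unit named `nm`.
# Convolutions feeding a normalization layer are bias-free (the norm's
# shift parameter is the bias); a conv bias there would receive exactly zero
# gradient.
init_cnr <- function(p, nm, k, cin, cout) {
  p[[paste0(nm, "_W")]] <- he_init(k, cin, cout)
  p[[paste0(nm, "_g")]] <- rep(1, cout)
  p[[paste0(nm, "_e")]] <- numeric(cout)
  p
}

#' Build a segmentation model
#'
#' @param cfg a [model_config()].
#' @return A `segmatch_model` holding the configuration and a named flat list
#'   of parameter arrays. Identical seeds give bit-identical parameters.
#' @export
build_model <- function(cfg) {
  if (!inherits(cfg, "model_config")) cfg <- do.call(model_config, cfg)
  ch <- cfg$base_channels * 2^(0:cfg$depth)
  p <- list()
  with_seed(derive_seed(cfg$seed, 0L, salt = 31L), {
    p <- init_cnr(p, "stem", 3, 3, ch[1])
    for (d in seq_len(cfg$depth)) {
      p <- init_cnr(p, paste0("down", d), 3, ch[d], ch[d + 1])
      p <- init_cnr(p, paste0("res", d, "a"), 3, ch[d + 1], ch[d + 1])
      p <- init_cnr(p, paste0("res", d, "b"), 3, ch[d + 1], ch[d + 1])
      # 1x1 channel projection after nearest-neighbour upsampling; the 3x3
      # fuse conv after the skip addition does the spatial mixing
      p <- init_cnr(p, paste0("up", d), 1, ch[d + 1], ch[d])
      p <- init_cnr(p, paste0("fuse", d), 3, ch[d], ch[d])
    }
    p$head_W <- he_init(1, ch[1], cfg$n_classes)
    p$head_b <- numeric(cfg$n_classes)
  })
  norm_units <- grep("_g$", names(p), value = TRUE)
  stats <- lapply(norm_units, function(nm)
    list(mean = numeric(length(p[[nm]])), var = rep(1, length(p[[nm]]))))
  names(stats) <- sub("_g$", "", norm_units)
  structure(list(cfg = cfg, params = p, stats = stats),
            class = "segmatch_model")
}

# ---- differentiable primitives -------------------------------------------

# Batch normalization over the (H, W, N) axes per channel. In training mode
# the batch statistics normalize and the running statistics receive an
# exponential update (momentum 0.1); in evaluation/attack mode the running
# statistics are used, which keeps per-image gradients independent during
# the adversarial refinement.
bn_fw <- function(x, g, b, stats, training, eps = 1e-5, mom = 0.1) {
  d <- dim(x); hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  m <- matrix(x, hw)
  chpat <- rep(seq_len(C), N)
  if (training) {
    mu <- rowsum(colMeans(m), chpat)[, 1] / N
    ex2 <- rowsum(colMeans(m * m), chpat)[, 1] / N
    v <- pmax(ex2 - mu^2, 0)
    stats <- list(mean = (1 - mom) * stats$mean + mom * mu,
                  var = (1 - mom) * stats$var + mom * v)
  } else {
    mu <- stats$mean; v <- stats$var
  }
  sdv <- sqrt(v + eps)
  xh <- (m - rep(mu[chpat], each = hw)) / rep(sdv[chpat], each = hw)
  y <- xh * rep(g[chpat], each = hw) + rep(b[chpat], each = hw)
  list(y = array(y, d), stats = stats,
       cache = list(xh = xh, sdv = sdv, chpat = chpat, d = d,
                    training = training))
}

bn_bw <- function(dy, cache, g) {
  d <- cache$d; hw <- d[1] * d[2]; N <- d[4]
  dym <- matrix(dy, hw)
  gcol <- g[cache$chpat]
  dxh <- dym * rep(gcol, each = hw)
  sd_col <- rep(cache$sdv[cache$chpat], each = hw)
  if (cache$training) {
    M <- hw * N
    s1 <- rowsum(colSums(dxh), cache$chpat)[, 1] / M
    s2 <- rowsum(colSums(dxh * cache$xh), cache$chpat)[, 1] / M
    dx <- (dxh - rep(s1[cache$chpat], each = hw) -
             cache$xh * rep(s2[cache$chpat], each = hw)) / sd_col
  } else {
    dx <- dxh / sd_col
  }
  dg <- rowsum(colSums(dym * cache$xh), cache$chpat)[, 1]
  db <- rowsum(colSums(dym), cache$chpat)[, 1]
  list(dx = array(dx, d), dg = unname(dg), db = unname(db))
}

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}

upsample2_bw <- function(dy) {
  d <- dim(dy)
  oi <- seq(1, d[1], 2); oj <- seq(1, d[2], 2)
  dy[oi, oj, , , drop = FALSE] + dy[oi + 1, oj, , , drop = FALSE] +
    dy[oi, oj + 1, , , drop = FALSE] + dy[oi + 1, oj + 1, , , drop = FALSE]
}

# conv + batch norm + ReLU with caches for the backward pass
cnr_fw <- function(x, p, stats, nm, stride = 1L, training = FALSE) {
  W <- p[[paste0(nm, "_W")]]
  z <- cpp_conv_fw(x, W, numeric(dim(W)[4]), stride)
  no <- bn_fw(z, p[[paste0(nm, "_g")]], p[[paste0(nm, "_e")]], stats[[nm]],
              training)
  mask <- no$y > 0
  stats[[nm]] <- no$stats
  list(y = no$y * mask, stats = stats,
       cache = list(x = x, norm = no$cache, mask = mask, stride = stride,
                    nm = nm))
}

cnr_bw <- function(dy, cache, p, grads) {
  nm <- cache$nm
  nb <- bn_bw(dy * cache$mask, cache$norm, p[[paste0(nm, "_g")]])
  cb <- cpp_conv_bw(cache$x, p[[paste0(nm, "_W")]], nb$dx, cache$stride)
  grads[[paste0(nm, "_W")]] <- grads[[paste0(nm, "_W")]] + cb$dw
  grads[[paste0(nm, "_g")]] <- grads[[paste0(nm, "_g")]] + nb$dg
  grads[[paste0(nm, "_e")]] <- grads[[paste0(nm, "_e")]] + nb$db
  list(dx = cb$dx, grads = grads)
}

as_batch <- function(x) {
  if (length(dim(x)) == 3) array(x, c(dim(x), 1L)) else x
}

# ---- full network ---------------------------------------------------------

# Forward pass over a [H, W, C, N] batch; returns logits and, on request,
# every cache needed for the exact backward pass.
model_forward <- function(model, x, want_cache = FALSE, training = FALSE) {
  p <- model$params; D <- model$cfg$depth
  stats <- model$stats
  x <- as_batch(x)
  d <- dim(x)
  if (any(!is.finite(x))) stop("non-finite input", call. = FALSE)
  if (d[1] %% 2^D != 0 || d[2] %% 2^D != 0)
    stop("input size must be a multiple of 2^depth", call. = FALSE)
  caches <- list()

  st <- cnr_fw(x, p, stats, "stem", 1L, training)
  stats <- st$stats
  caches[["stem"]] <- st$cache
  skips <- vector("list", D + 1)
  skips[[1]] <- st$y
  cur <- st$y
  for (dd in seq_len(D)) {
    dn <- cnr_fw(cur, p, stats, paste0("down", dd), 2L, training)
    stats <- dn$stats
    caches[[paste0("down", dd)]] <- dn$cache
    ra <- cnr_fw(dn$y, p, stats, paste0("res", dd, "a"), 1L, training)
    stats <- ra$stats
    caches[[paste0("res", dd, "a")]] <- ra$cache
    bnm <- paste0("res", dd, "b")
    rz <- cpp_conv_fw(ra$y, p[[paste0(bnm, "_W")]],
                      numeric(dim(p[[paste0(bnm, "_W")]])[4]), 1L)
    rn <- bn_fw(rz, p[[paste0(bnm, "_g")]], p[[paste0(bnm, "_e")]],
                stats[[bnm]], training)
    stats[[bnm]] <- rn$stats
    summ <- dn$y + rn$y
    mask <- summ > 0
    out <- summ * mask
    caches[[bnm]] <- list(x = ra$y, norm = rn$cache, mask = mask)
    skips[[dd + 1]] <- out
    cur <- out
  }
  for (dd in rev(seq_len(D))) {
    u <- upsample2(cur)
    uo <- cnr_fw(u, p, stats, paste0("up", dd), 1L, training)
    stats <- uo$stats
    caches[[paste0("up", dd)]] <- uo$cache
    s <- uo$y + skips[[dd]]
    fo <- cnr_fw(s, p, stats, paste0("fuse", dd), 1L, training)
    stats <- fo$stats
    caches[[paste0("fuse", dd)]] <- fo$cache
    cur <- fo$y
  }
  logits <- cpp_conv_fw(cur, p$head_W, p$head_b, 1L)
  caches[["head"]] <- cur
  if (want_cache || training)
    list(logits = logits, caches = caches, stats = stats)
  else logits
}

# Exact reverse of model_forward. Returns parameter gradients plus the
# gradient with respect to the input batch (needed by the FGSM attacks).
model_backward <- function(model, caches, dlogits) {
  p <- model$params; D <- model$cfg$depth
  grads <- lapply(p, function(a) if (is.null(dim(a))) numeric(length(a))
                  else array(0, dim(a)))
  hb <- cpp_conv_bw(caches[["head"]], p$head_W, as_batch(dlogits), 1L)
  grads$head_W <- hb$dw; grads$head_b <- hb$db
  dcur <- hb$dx
  dskips <- vector("list", D + 1)
  for (dd in seq_len(D)) {
    fb <- cnr_bw(dcur, caches[[paste0("fuse", dd)]], p, grads)
    grads <- fb$grads
    dskips[[dd]] <- fb$dx              # gradient into the skip connection
    ub <- cnr_bw(fb$dx, caches[[paste0("up", dd)]], p, grads)
    grads <- ub$grads
    dcur <- upsample2_bw(ub$dx)
  }
  for (dd in rev(seq_len(D))) {
    dout <- dcur
    if (!is.null(dskips[[dd + 1]])) dout <- dout + dskips[[dd + 1]]
    cb <- caches[[paste0("res", dd, "b")]]
    dsum <- dout * cb$mask
    nb <- bn_bw(dsum, cb$norm, p[[paste0("res", dd, "b_g")]])
    cv <- cpp_conv_bw(cb$x, p[[paste0("res", dd, "b_W")]], nb$dx, 1L)
    grads[[paste0("res", dd, "b_W")]] <- grads[[paste0("res", dd, "b_W")]] + cv$dw
    grads[[paste0("res", dd, "b_g")]] <- grads[[paste0("res", dd, "b_g")]] + nb$dg
    grads[[paste0("res", dd, "b_e")]] <- grads[[paste0("res", dd, "b_e")]] + nb$db
    ab <- cnr_bw(cv$dx, caches[[paste0("res", dd, "a")]], p, grads)
    grads <- ab$grads
    ddn <- ab$dx + dsum                # residual shortcut
    db <- cnr_bw(ddn, caches[[paste0("down", dd)]], p, grads)
    grads <- db$grads
    dcur <- db$dx
  }
  dstem <- dcur
  if (!is.null(dskips[[1]])) dstem <- dstem + dskips[[1]]
  sb <- cnr_bw(dstem, caches[["stem"]], p, grads)
  list(grads = sb$grads, dx = sb$dx)
}

#' Forward pass of a segmentation model
#'
#' Generic so that alternative model objects (e.g. the frozen linear
#' per-pixel classifier used as an analytic oracle in the tests) can plug
#' into the attack and training machinery.
#'
#' @param model a model object.
#' @param x H x W x C image array in [0,1], or an H x W x C x N batch.
#' @param ... passed to methods.
#' @return Logit array, H x W x L (or H x W x L x N for a batch input).
#' @export
forward <- function(model, x, ...) UseMethod("forward")

#' @export
forward.segmatch_model <- function(model, x, ...) {
  single <- length(dim(x)) == 3
  out <- model_forward(model, x)
  if (single) array(out, dim(out)[1:3]) else out
}

#' Gradient of a scalar loss with respect to the model input
#'
#' Given the gradient of the loss at the logits, back-propagates through the
#' frozen model and returns the gradient at the input image. Parameters are
#' not modified.
#'
#' @param model a model object.
#' @param x input image (H x W x C) or batch.
#' @param dlogits gradient of the loss w.r.t. the logits, same geometry as
#'   `forward(model, x)`.
#' @param ... passed to methods.
#' @return Array with the shape of `x`.
#' @export
input_gradient <- function(model, x, dlogits, ...) UseMethod("input_gradient")

#' @export
input_gradient.segmatch_model <- function(model, x, dlogits, ...) {
  single <- length(dim(x)) == 3
  fc <- model_forward(model, x, want_cache = TRUE)
  bk <- model_backward(model, fc$caches, dlogits)
  if (single) array(bk$dx, dim(x)) else bk$dx
}

#' Save / load a model checkpoint
#'
#' Checkpoints are plain JSON (configuration plus flattened parameter
#' arrays), so they are text, portable and diffable.
#'
#' @param model a `segmatch_model`.
#' @param path file path.
#' @return `save_model` invisibly returns `path`; `load_model` returns the
#'   rebuilt model.
#' @export
save_model <- function(model, path) {
  rec <- list(cfg = unclass(model$cfg),
              params = lapply(model$params, function(a)
                list(dim = if (is.null(dim(a))) length(a) else dim(a),
                     data = as.numeric(a))),
              stats = model$stats)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  rec <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, rec$cfg)
  params <- lapply(rec$params, function(e) {
    if (length(e$dim) > 1) array(e$data, e$dim) else as.numeric(e$data)
  })
  stats <- lapply(rec$stats, function(e)
    list(mean = as.numeric(e$mean), var = as.numeric(e$var)))
  structure(list(cfg = cfg, params = params, stats = stats),
            class = "segmatch_model")
}
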