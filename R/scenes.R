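#' Synthetic instrument-like scene configuration
#'
#' Describes the generator for seeded synthetic scenes: bright elongated
#' capsule-shaped objects (optionally carrying a specular highlight streak)
#' over a smooth low-frequency textured background with i.i.d. Gaussian
#' pixel noise. The geometry emulates the structure of endoscopic instrument
#' imagery (tool shafts over tissue) without copying any dataset.
#'
#' @param height,width scene size in pixels (>= 16).
#' @param n_classes number of classes including background (class 0).
#' @param n_objects_range inclusive integer interval for the object count.
#' @param object_width_range inclusive interval for capsule width in pixels.
#' @param highlight_probability probability that an object carries a brighter
#'   specular streak (the streak changes the image, never the mask).
#' @param background_texture_scale spatial scale (pixels) of the background
#'   texture; larger values give smoother backgrounds.
#' @param noise_sd standard deviation of additive Gaussian noise in [0,1]
#'   intensity units; images are clipped back to [0,1].
#' @param seed master integer seed; scene `index` uses a derived substream so
#'   regeneration is order-independent and bit-identical.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(height = 64, width = 64, n_classes = 2,
                         n_objects_range = c(1, 3),
                         object_width_range = c(4, 8),
                         highlight_probability = 0.5,
                         background_texture_scale = 16,
                         noise_sd = 0.05, seed = 1) {
  cfg <- list(height = as.integer(height), width = as.integer(width),
              n_classes = as.integer(n_classes),
              n_objects_range = as.integer(n_objects_range),
              object_width_range = as.numeric(object_width_range),
              highlight_probability = as.numeric(highlight_probability),
              background_texture_scale = as.numeric(background_texture_scale),
              noise_sd = as.numeric(noise_sd), seed = as.integer(seed))
  stopifnot_config(cfg$height >= 16 && cfg$width >= 16,
                   "scene dimensions must be at least 16 pixels")
  stopifnot_config(cfg$n_classes >= 2, "n_classes must be >= 2")
  stopifnot_config(length(cfg$n_objects_range) == 2 &&
                     cfg$n_objects_range[1] >= 0 &&
                     cfg$n_objects_range[1] <= cfg$n_objects_range[2],
                   "invalid n_objects_range")
  stopifnot_config(cfg$highlight_probability >= 0 &&
                     cfg$highlight_probability <= 1,
                   "highlight_probability must lie in [0,1]")
  stopifnot_config(cfg$noise_sd >= 0 && cfg$noise_sd <= 1,
                   "noise_sd must lie in [0,1]")
  class(cfg) <- "scene_config"
  cfg
}

# Smooth low-frequency field: coarse iid grid upsampled bilinearly.
low_freq_field <- function(h, w, scale) {
  gh <- max(2L, ceiling(h / scale) + 1L)
  gw <- max(2L, ceiling(w / scale) + 1L)
  resize_bilinear(matrix(runif(gh * gw), gh, gw), h, w)
}

# Paint a capsule (segment dilated by radius) into image/mask in place.
# Returns list(img, mask). Colour is length-3; cls an integer class id.
paint_capsule <- function(img, mask, cx, cy, angle, len, radius, colour, cls) {
  h <- nrow(mask); w <- ncol(mask)
  ux <- cos(angle); uy <- sin(angle)
  py <- matrix(seq_len(h), h, w) - cy
  px <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  tproj <- px * ux + py * uy
  tclamp <- pmin(pmax(tproj, -len / 2), len / 2)
  dx <- px - tclamp * ux
  dy <- py - tclamp * uy
  inside <- (dx * dx + dy * dy) <= radius^2
  if (any(inside)) {
    for (c in 1:3) {
      ch <- img[, , c]
      ch[inside] <- colour[c]
      img[, , c] <- ch
    }
    if (!is.null(cls)) mask[inside] <- cls
  }
  list(img = img, mask = mask)
}

#' Generate one synthetic scene
#'
#' Deterministic in `(config, index)`: the scene is drawn from a substream
#' derived from `config$seed` and `index`, so the same pair always returns
#' bit-identical output regardless of call order.
#'
#' @param config a [scene_config()].
#' @param index positive integer scene index.
#' @return A list with `image` (H x W x 3 array in [0,1]) and `mask`
#'   (H x W integer matrix of class ids, 0 = background).
#' @export
generate_scene <- function(config, index) {
  if (!inherits(config, "scene_config")) config <- do.call(scene_config, config)
  h <- config$height; w <- config$width
  with_seed(derive_seed(config$seed, index, salt = 11L), {
    # background: low-frequency texture with a mild random per-channel tint
    base <- low_freq_field(h, w, config$background_texture_scale)
    tint <- runif(3, 0.85, 1.15)
    lo <- runif(1, 0.05, 0.25); hi <- runif(1, 0.35, 0.55)
    img <- array(0, c(h, w, 3))
    for (c in 1:3) img[, , c] <- (lo + base * (hi - lo)) * tint[c]
    mask <- matrix(0L, h, w)

    n_obj <- if (config$n_objects_range[1] == config$n_objects_range[2]) {
      config$n_objects_range[1]
    } else {
      sample(config$n_objects_range[1]:config$n_objects_range[2], 1)
    }
    if (n_obj > 0) {
      for (k in seq_len(n_obj)) {
        width_k <- runif(1, config$object_width_range[1],
                         config$object_width_range[2])
        len_k <- width_k * runif(1, 3, 6)          # elongated: length >= 3x width
        cx <- runif(1, 1, w); cy <- runif(1, 1, h)
        ang <- runif(1, 0, pi)
        cls <- if (config$n_classes == 2) 1L else
          sample(seq_len(config$n_classes - 1L), 1)
        # bright metallic body with a per-class colour cast
        base_i <- runif(1, 0.6, 0.9)
        cast <- 0.85 + 0.3 * ((cls * c(1, 2, 3)) %% 4) / 4
        colour <- pmin(base_i * cast, 1)
        out <- paint_capsule(img, mask, cx, cy, ang, len_k, width_k / 2,
                             colour, cls)
        img <- out$img; mask <- out$mask
        if (runif(1) < config$highlight_probability) {
          # specular streak: thinner, brighter, along the same axis; image only
          off <- runif(1, -width_k / 4, width_k / 4)
          out <- paint_capsule(img, mask,
                               cx - off * sin(ang), cy + off * cos(ang), ang,
                               len_k * runif(1, 0.4, 0.8), width_k / 6 + 0.5,
                               rep(runif(1, 0.95, 1), 3), NULL)
          img <- out$img
        }
      }
    }
    if (config$noise_sd > 0)
      img <- img + array(rnorm(h * w * 3, sd = config$noise_sd), c(h, w, 3))
    list(image = clamp01(img), mask = mask)
  })
}

#' Generate a semi-supervised synthetic dataset
#'
#' Draws `n_total` scenes and keeps annotations for a random
#' `floor(labelled_fraction * n_total)` of them; the remaining scenes have
#' their masks discarded and form the unlabelled pool. Fully deterministic
#' under `config$seed`.
#'
#' @param config a [scene_config()].
#' @param n_total total number of scenes (>= 1).
#' @param labelled_fraction fraction in (0, 1] of scenes keeping their masks.
#' @return A list of class `seg_dataset` with `labelled` (list of
#'   `list(image, mask)`), `unlabelled` (list of images), `n_classes`, and the
#'   drawn `labelled_idx` / `unlabelled_idx`.
#' @export
generate_dataset <- function(config, n_total, labelled_fraction) {
  stopifnot_config(n_total >= 1, "n_total must be >= 1")
  stopifnot_config(labelled_fraction > 0 && labelled_fraction <= 1,
                   "labelled_fraction must lie in (0, 1]")
  n_lab <- floor(labelled_fraction * n_total)
  stopifnot_config(n_lab >= 1, "labelled_fraction leaves no labelled scene")
  lab_idx <- with_seed(derive_seed(config$seed, 0L, salt = 23L),
                       sort(sample(n_total, n_lab)))
  unlab_idx <- setdiff(seq_len(n_total), lab_idx)
  scenes <- lapply(seq_len(n_total), function(i) generate_scene(config, i))
  ds <- list(labelled = scenes[lab_idx],
             unlabelled = lapply(scenes[unlab_idx], `[[`, "image"),
             n_classes = config$n_classes,
             labelled_idx = lab_idx, unlabelled_idx = unlab_idx)
  class(ds) <- "seg_dataset"
  ds
}
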