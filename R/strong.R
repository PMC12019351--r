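#' Hand-crafted photometric strong augmentations
#'
#' Strong augmentations initialise the consistency branch for unlabelled
#' images. They are purely photometric (per-pixel / per-channel intensity or
#' small-kernel changes), so the segmentation target is invariant under them
#' by construction and no inverse transform is needed. The pool follows the
#' RandAugment photometric family, defined on the continuous [0,1] domain:
#' contrast, brightness, colour and sharpness factors blend towards the mean
#' intensity, black, grayscale and a box-smoothed image respectively; random
#' noise adds i.i.d. Gaussian noise; posterize quantizes each channel to `b`
#' bits (`b >= 8` is the identity on continuous images); solarize inverts
#' pixels strictly above a threshold. Every op clamps its output to [0,1].
#'
#' @name augment_strong
NULL

STRONG_OPS <- c("contrast", "brightness", "colour", "sharpness",
                "random_noise", "posterize", "solarize")

#' Default magnitude ranges for photometric ops
#'
#' Mild, visually plausible settings: blend factors in [0.6, 1.4], noise sd
#' up to 0.05, posterization no coarser than 3 bits, solarize threshold at
#' least 0.7. All ranges can be overridden through the configuration.
#'
#' @return Named list of closed intervals, one per op.
#' @export
default_strong_ranges <- function() {
  list(contrast = c(0.6, 1.4), brightness = c(0.6, 1.4), colour = c(0.6, 1.4),
       sharpness = c(0.6, 1.4), random_noise = c(0, 0.05),
       posterize = c(3, 8), solarize = c(0.7, 1.0))
}

#' Sample a strong augmentation
#'
#' Draws `n_ops` ops without replacement from the photometric pool and a
#' uniform magnitude within each op's configured range (posterize bit-depths
#' are integer).
#'
#' @param ranges named list of magnitude ranges (see
#'   [default_strong_ranges()]); its names define the pool.
#' @param n_ops number of composed ops (default 3).
#' @return A `strong_augmentation`: list of `list(name, magnitude)`.
#' @export
sample_strong_augmentation <- function(ranges = default_strong_ranges(),
                                       n_ops = 3) {
  pool <- names(ranges)
  stopifnot_config(all(pool %in% STRONG_OPS), "unknown photometric op")
  stopifnot_config(n_ops <= length(pool), "n_ops exceeds the op pool")
  chosen <- if (length(pool) == n_ops) sample(pool) else sample(pool, n_ops)
  ops <- lapply(chosen, function(nm) {
    r <- ranges[[nm]]
    mag <- if (nm == "posterize") sample(seq(r[1], r[2]), 1) else runif(1, r[1], r[2])
    list(name = nm, magnitude = mag)
  })
  structure(ops, class = "strong_augmentation")
}

apply_photometric_op <- function(name, magnitude, x) {
  out <- switch(name,
    brightness = x * magnitude,
    contrast = {
      mu <- mean(x)
      mu + (x - mu) * magnitude
    },
    colour = {
      gray <- (x[, , 1] + x[, , 2] + x[, , 3]) / 3
      g3 <- array(gray, dim(x))
      g3 + (x - g3) * magnitude
    },
    sharpness = {
      sm <- x
      for (c in seq_len(dim(x)[3])) sm[, , c] <- box_smooth3(x[, , c])
      sm + (x - sm) * magnitude
    },
    random_noise = x + array(rnorm(length(x), sd = magnitude), dim(x)),
    posterize = {
      b <- round(magnitude)
      if (b >= 8) x else {
        n <- 2^b
        pmin(floor(x * n), n - 1) / (n - 1)
      }
    },
    solarize = ifelse(x > magnitude, 1 - x, x),
    stop("unknown photometric op: ", name, call. = FALSE))
  clamp01(out)
}

# 3x3 box smoothing with edge replication; the only small-kernel op.
box_smooth3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- m[c(1, seq_len(h), h), c(1, seq_len(w), w)]
  acc <- matrix(0, h, w)
  for (dy in 0:2) for (dx in 0:2)
    acc <- acc + p[dy + seq_len(h), dx + seq_len(w)]
  acc / 9
}

#' Apply a strong augmentation composition
#'
#' Ops are applied in sampled order; the result is clamped to [0,1] after
#' every op, so repeated application can never leave the valid image range.
#'
#' @param a a `strong_augmentation` from [sample_strong_augmentation()].
#' @param x H x W x 3 image array in [0,1].
#' @return Augmented image in [0,1], same shape.
#' @export
apply_strong_init <- function(a, x) {
  for (op in a) x <- apply_photometric_op(op$name, op$magnitude, x)
  x
}

#' Serialize / deserialize a strong augmentation
#' @param a a `strong_augmentation`.
#' @return JSON string / rebuilt object.
#' @export
strong_to_json <- function(a) {
  jsonlite::toJSON(lapply(a, function(o) list(name = o$name,
                                              magnitude = o$magnitude)),
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname strong_to_json
#' @param json JSON string produced by `strong_to_json`.
#' @export
strong_from_json <- function(json) {
  rec <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  structure(lapply(rec, function(o) list(name = o$name, magnitude = o$magnitude)),
            class = "strong_augmentation")
}
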