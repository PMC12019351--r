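#' Invertible weak spatial augmentations
#'
#' Weak augmentations are simple spatial transforms applied to unlabelled
#' images before the pseudo-labelling forward pass. Because segmentation is
#' equivariant (not invariant) to spatial transforms, the model output must be
#' mapped back to the original frame with the exact inverse transform before
#' it can be compared with the strong branch; each transform therefore ships
#' with its inverse and a validity mask stating on which pixels the inversion
#' is faithful.
#'
#' The default set contains the dihedral transforms (flips and multiples of
#' 90 degrees), whose inverses are exact permutations, plus `crop_resize`.
#' A free-angle rotation (`rot_free`) with bilinear resampling and a shrunken
#' validity mask is available but not enabled by default, since resampling
#' breaks bit-exact inversion.
#'
#' @name augment_weak
NULL

WEAK_KINDS <- c("identity", "hflip", "vflip", "rot90", "rot180", "rot270",
                "crop_resize")
DIHEDRAL_KINDS <- c("identity", "hflip", "vflip", "rot90", "rot180", "rot270")

weak_transform <- function(kind, params = list()) {
  structure(list(kind = kind, params = params), class = "weak_transform")
}

#' Sample a weak spatial transform
#'
#' Draws one transform kind uniformly from the enabled set; `crop_resize`
#' rectangles are sampled to cover at least half of each image dimension
#' (0-based, half-open pixel coordinates).
#'
#' @param image_shape integer vector `c(H, W)`, both >= 16.
#' @param enabled character vector of transform kinds to draw from.
#' @return A `weak_transform` object.
#' @export
sample_weak_transform <- function(image_shape, enabled = WEAK_KINDS) {
  stopifnot_config(length(enabled) >= 1, "enabled transform set is empty")
  bad <- setdiff(enabled, c(WEAK_KINDS, "rot_free"))
  stopifnot_config(length(bad) == 0,
                   paste("unknown transform kind:", paste(bad, collapse = ", ")))
  h <- image_shape[1]; w <- image_shape[2]
  stopifnot_config(h >= 16 && w >= 16, "image dimensions must be >= 16")
  kind <- if (length(enabled) == 1) enabled else sample(enabled, 1)
  params <- list()
  if (kind == "crop_resize") {
    ch <- sample(ceiling(h / 2):h, 1)
    cw <- sample(ceiling(w / 2):w, 1)
    params <- list(y0 = sample(0:(h - ch), 1), x0 = sample(0:(w - cw), 1),
                   ch = ch, cw = cw)
  } else if (kind == "rot_free") {
    params <- list(angle = runif(1, -pi / 6, pi / 6))
  }
  weak_transform(kind, params)
}

rot_ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]

apply_spatial_mat <- function(kind, m) {
  switch(kind,
    identity = m,
    hflip = m[, ncol(m):1, drop = FALSE],
    vflip = m[nrow(m):1, , drop = FALSE],
    rot90 = rot_ccw(m),
    rot180 = m[nrow(m):1, ncol(m):1, drop = FALSE],
    rot270 = rot_ccw(rot_ccw(rot_ccw(m))),
    stop("not a dihedral kind"))
}

INVERSE_KIND <- c(identity = "identity", hflip = "hflip", vflip = "vflip",
                  rot90 = "rot270", rot180 = "rot180", rot270 = "rot90")

# Bilinear sample arr (H x W x C) at fractional 1-based coords (ys, xs);
# out-of-bounds samples return 0 and are flagged in the validity attribute.
bilinear_sample <- function(arr, ys, xs) {
  d <- dim(arr); h <- d[1]; w <- d[2]; nc <- d[3]
  valid <- ys >= 1 & ys <= h & xs >= 1 & xs <= w
  ysc <- pmin(pmax(ys, 1), h); xsc <- pmin(pmax(xs, 1), w)
  y0 <- pmin(floor(ysc), h - 1); x0 <- pmin(floor(xsc), w - 1)
  fy <- ysc - y0; fx <- xsc - x0
  out <- array(0, c(dim(valid), nc))
  for (c in seq_len(nc)) {
    p <- arr[, , c]
    v <- p[cbind(c(y0), c(x0))] * c((1 - fy) * (1 - fx)) +
      p[cbind(c(y0 + 1), c(x0))] * c(fy * (1 - fx)) +
      p[cbind(c(y0), c(x0 + 1))] * c((1 - fy) * fx) +
      p[cbind(c(y0 + 1), c(x0 + 1))] * c(fy * fx)
    v[!valid] <- 0
    out[, , c] <- v
  }
  attr(out, "valid") <- valid
  out
}

rotate_free <- function(arr, angle) {
  d <- dim(arr); h <- d[1]; w <- d[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  # inverse mapping: sample source at R(-angle) * (target - centre)
  ys <- cy + cos(angle) * (yy - cy) - sin(angle) * (xx - cx)
  xs <- cx + sin(angle) * (yy - cy) + cos(angle) * (xx - cx)
  bilinear_sample(arr, ys, xs)
}

#' Apply a weak transform to an image or score map
#'
#' @param t a `weak_transform`.
#' @param x H x W x C array (image or logits).
#' @return The transformed array (dihedral transforms permute pixels exactly).
#' @export
apply_weak <- function(t, x) {
  d <- dim(x)
  if (t$kind %in% DIHEDRAL_KINDS) {
    chans <- lapply(seq_len(d[3]), function(c) apply_spatial_mat(t$kind, x[, , c]))
    return(array(unlist(chans), c(dim(chans[[1]]), d[3])))
  }
  if (t$kind == "crop_resize") {
    p <- t$params
    if (p$y0 < 0 || p$x0 < 0 || p$y0 + p$ch > d[1] || p$x0 + p$cw > d[2])
      stop("crop rectangle outside image bounds", call. = FALSE)
    crop <- x[(p$y0 + 1):(p$y0 + p$ch), (p$x0 + 1):(p$x0 + p$cw), , drop = FALSE]
    return(resize_bilinear(crop, d[1], d[2]))
  }
  if (t$kind == "rot_free") {
    out <- rotate_free(x, t$params$angle)
    attr(out, "valid") <- NULL
    return(out)
  }
  stop("unknown transform kind: ", t$kind, call. = FALSE)
}

#' Invert a weak transform on model outputs
#'
#' Maps logits computed in the transformed frame back to the original frame
#' and reports the validity region. Dihedral inverses are exact pixel
#' permutations (validity all `TRUE`). For `crop_resize` the logits are
#' resized back to the crop rectangle and embedded at its position; pixels
#' outside the rectangle were never observed and are marked invalid so they
#' are excluded from the confident set downstream.
#'
#' @param t a `weak_transform`.
#' @param logits H' x W' x L array produced on the transformed geometry.
#' @param orig_shape integer `c(H, W)` of the original image.
#' @return `list(logits, valid)` with `logits` H x W x L and `valid` an
#'   H x W logical matrix.
#' @export
invert_on_logits <- function(t, logits, orig_shape = dim(logits)[1:2]) {
  h <- orig_shape[1]; w <- orig_shape[2]
  if (t$kind %in% DIHEDRAL_KINDS) {
    dexp <- if (t$kind %in% c("rot90", "rot270")) c(w, h) else c(h, w)
    if (!all(dim(logits)[1:2] == dexp))
      stop("logit geometry does not match the transform", call. = FALSE)
    inv <- weak_transform(INVERSE_KIND[[t$kind]])
    return(list(logits = apply_weak(inv, logits),
                valid = matrix(TRUE, h, w)))
  }
  if (t$kind == "crop_resize") {
    if (!all(dim(logits)[1:2] == c(h, w)))
      stop("logit geometry does not match the transform", call. = FALSE)
    p <- t$params
    back <- resize_bilinear(logits, p$ch, p$cw)
    if (length(dim(back)) == 2) back <- array(back, c(p$ch, p$cw, 1L))
    out <- array(0, c(h, w, dim(logits)[3]))
    out[(p$y0 + 1):(p$y0 + p$ch), (p$x0 + 1):(p$x0 + p$cw), ] <- back
    valid <- matrix(FALSE, h, w)
    valid[(p$y0 + 1):(p$y0 + p$ch), (p$x0 + 1):(p$x0 + p$cw)] <- TRUE
    return(list(logits = out, valid = valid))
  }
  if (t$kind == "rot_free") {
    out <- rotate_free(logits, -t$params$angle)
    valid <- attr(out, "valid")
    attr(out, "valid") <- NULL
    # forward rotation also lost corner content; intersect both validity maps
    fwd_valid <- attr(rotate_free(array(1, c(h, w, 1)), t$params$angle), "valid")
    return(list(logits = out, valid = valid & fwd_valid))
  }
  stop("unknown transform kind: ", t$kind, call. = FALSE)
}

#' Serialize / deserialize a weak transform
#'
#' @param t a `weak_transform`.
#' @return `weak_to_json` returns a JSON string; `weak_from_json` rebuilds the
#'   transform object.
#' @export
weak_to_json <- function(t) {
  jsonlite::toJSON(list(kind = t$kind, params = t$params), auto_unbox = TRUE,
                   digits = NA)
}

#' @rdname weak_to_json
#' @param json JSON string produced by `weak_to_json`.
#' @export
weak_from_json <- function(json) {
  rec <- jsonlite::fromJSON(json)
  weak_transform(rec$kind, as.list(rec$params))
}
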