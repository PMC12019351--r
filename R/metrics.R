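#' Dice similarity coefficient for one class
#'
#' `2 |P intersect G| / (|P| + |G|)` on the binary masks of class `cls`;
#' defined as 1 when both masks are empty.
#'
#' @param pred,gt H x W integer label masks.
#' @param cls class id whose binary mask is scored (default 1).
#' @return Dice fraction in [0,1].
#' @export
dice_score <- function(pred, gt, cls = 1L) {
  p <- pred == cls; g <- gt == cls
  np <- sum(p); ng <- sum(g)
  if (np + ng == 0) return(1)
  2 * sum(p & g) / (np + ng)
}

# Boundary pixels of a logical foreground mask: foreground pixels with at
# least one non-foreground 4-neighbour, the image border counting as
# non-foreground.
boundary_pixels <- function(fg) {
  h <- nrow(fg); w <- ncol(fg)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- fg
  inner <- pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)] &
    pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)]
  which(fg & !inner, arr.ind = TRUE)
}

#' Normalized Surface Dice with a pixel tolerance
#'
#' Boundary pixel sets are extracted from the foreground (`mask != 0`) of
#' each mask using 4-connectivity with the image border treated as
#' background. The score is the fraction of boundary pixels of either mask
#' lying within Euclidean pixel-centre distance `tau` of the other mask's
#' boundary. Conventions: 1 if both masks are empty, 0 if exactly one is.
#'
#' @param pred,gt H x W integer label masks (foreground = nonzero).
#' @param tau distance tolerance in pixels (>= 0).
#' @return NSD fraction in [0,1].
#' @export
nsd_score <- function(pred, gt, tau) {
  stopifnot_config(tau >= 0, "tau must be >= 0")
  bp <- boundary_pixels(pred != 0)
  bg <- boundary_pixels(gt != 0)
  if (nrow(bp) == 0 && nrow(bg) == 0) return(1)
  if (nrow(bp) == 0 || nrow(bg) == 0) return(0)
  d2 <- outer(bp[, 1], bg[, 1], "-")^2 + outer(bp[, 2], bg[, 2], "-")^2
  tol2 <- tau^2
  np <- nrow(bp); ng <- nrow(bg)
  min_p <- d2[cbind(seq_len(np), max.col(-d2, ties.method = "first"))]
  min_g <- d2[cbind(max.col(-t(d2), ties.method = "first"), seq_len(ng))]
  (sum(min_p <= tol2) + sum(min_g <= tol2)) / (np + ng)
}

iou_class <- function(pred, gt, cls) {
  p <- pred == cls; g <- gt == cls
  u <- sum(p | g)
  if (u == 0) return(NA_real_)
  sum(p & g) / u
}

#' Multi-class IoU report (Ch_IoU, ISI_IoU, mc_IoU)
#'
#' Per image, the Ch contribution is the mean IoU over the foreground classes
#' present in that image's ground truth; the ISI contribution averages over
#' classes present in the ground truth or the prediction (a spurious
#' predicted class contributes an IoU of 0, so `ISI_IoU <= Ch_IoU` whenever
#' predictions only add classes). Both are averaged over images. `mc_IoU`
#' flips the averaging order: each class's IoU is first averaged over the
#' images where the class appears (in ground truth or prediction), then the
#' class averages are averaged. Background (class 0) is excluded throughout.
#'
#' @param preds,gts aligned lists of H x W integer label masks.
#' @param n_classes total class count L (ids 0..L-1).
#' @return List with `ch_iou`, `isi_iou`, `mc_iou` and `per_class` (named
#'   vector of mean IoU per foreground class; `NaN` when a class never
#'   appears).
#' @export
multiclass_iou_report <- function(preds, gts, n_classes) {
  if (length(preds) != length(gts))
    stop("preds and gts have different lengths", call. = FALSE)
  fg <- seq_len(n_classes - 1L)
  ch <- isi <- numeric(length(preds))
  cls_sum <- cls_n <- numeric(n_classes - 1L)
  for (i in seq_along(preds)) {
    p <- preds[[i]]; g <- gts[[i]]
    in_gt <- fg[fg %in% g]
    in_any <- fg[fg %in% g | fg %in% p]
    iou_any <- vapply(in_any, function(c) iou_class(p, g, c), numeric(1))
    ch[i] <- if (length(in_gt) == 0) 1 else
      mean(iou_any[match(in_gt, in_any)])
    isi[i] <- if (length(in_any) == 0) 1 else mean(iou_any)
    if (length(in_any) > 0) {
      cls_sum[in_any] <- cls_sum[in_any] + iou_any
      cls_n[in_any] <- cls_n[in_any] + 1
    }
  }
  per_class <- cls_sum / cls_n
  names(per_class) <- as.character(fg)
  list(ch_iou = mean(ch), isi_iou = mean(isi),
       mc_iou = mean(per_class[cls_n > 0]), per_class = per_class)
}

#' Predict a hard label mask
#'
#' Per-pixel argmax of the model logits (ties resolve to the lowest class
#' id).
#'
#' @param model a model object.
#' @param image H x W x C image in [0,1].
#' @return H x W integer mask.
#' @export
predict_mask <- function(model, image) {
  logits <- forward(model, image)
  d <- dim(logits)
  m <- logits_to_mat(logits)
  matrix(max.col(m, ties.method = "first") - 1L, d[1], d[2])
}

#' Evaluate a model on a labelled test set
#'
#' Computes hard predictions by per-pixel argmax and reports image-averaged
#' foreground Dice (mean over classes present in ground truth or prediction,
#' background excluded), NSD on the foreground-vs-background boundary at
#' tolerance `tau`, and the IoU family.
#'
#' @param model a model object.
#' @param test_set list of `list(image, mask)` pairs.
#' @param tau NSD tolerance in pixels. The reference resolution uses 13; by
#'   default it is scaled proportionally to image width,
#'   `round(13 * W / 512)`, clamped to at least 1.
#' @param n_classes total class count L.
#' @return A `metric_report` list with fields `dice`, `nsd`, `tolerance`,
#'   `ch_iou`, `isi_iou`, `mc_iou`, `per_class_iou`.
#' @export
evaluate <- function(model, test_set, n_classes, tau = NULL) {
  w <- ncol(test_set[[1]]$mask)
  if (is.null(tau)) tau <- max(1, round(13 * w / 512))
  preds <- lapply(test_set, function(it) predict_mask(model, it$image))
  gts <- lapply(test_set, `[[`, "mask")
  fg <- seq_len(n_classes - 1L)
  dice_img <- mapply(function(p, g) {
    cls <- fg[fg %in% g | fg %in% p]
    if (length(cls) == 0) return(1)
    mean(vapply(cls, function(c) dice_score(p, g, c), numeric(1)))
  }, preds, gts)
  nsd_img <- mapply(function(p, g) nsd_score(p, g, tau), preds, gts)
  iou <- multiclass_iou_report(preds, gts, n_classes)
  structure(list(dice = mean(dice_img), nsd = mean(nsd_img), tolerance = tau,
                 ch_iou = iou$ch_iou, isi_iou = iou$isi_iou,
                 mc_iou = iou$mc_iou, per_class_iou = iou$per_class),
            class = "metric_report")
}
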