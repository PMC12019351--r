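#' Configuration profiles
#'
#' `paper_profile()` carries the full-scale reference settings (depth-6
#' model, 1000 epochs, batch 64, K = 25); `desk_profile()` is the scaled-down
#' CPU profile driving all tests (64 x 64 scenes, depth-2 model, 30 epochs,
#' batch 8, K = 3). Both are complete nested configuration documents; YAML
#' files override individual keys.
#'
#' @return Nested named list with sections `scene`, `data`, `model`, `train`,
#'   `adversarial`, `loss`, `metrics`, `profile`.
#' @export
desk_profile <- function() {
  list(profile = "desk",
       scene = list(height = 64, width = 64, n_classes = 2,
                    n_objects_range = c(1, 3), object_width_range = c(4, 8),
                    highlight_probability = 0.5,
                    background_texture_scale = 16, noise_sd = 0.05, seed = 1),
       data = list(n_total = 200, labelled_fraction = 0.1),
       model = list(depth = 2, base_channels = 8, seed = 1),
       train = list(epochs = 30, batch_size = 8, lr_ini = 0.01, eta = 0.7,
                    momentum = 0.95, seed = 1, temperature = 0.5,
                    threshold = 0.8, weak_enabled = TRUE,
                    strong_enabled = TRUE),
       adversarial = list(epsilon = 0.08, steps = 3, enabled = TRUE),
       loss = list(rampup_epochs = 9, w_max = 1.0, smooth = 1e-6),
       metrics = list(tolerance = NA))
}

#' @rdname desk_profile
#' @export
paper_profile <- function() {
  cfg <- desk_profile()
  cfg$profile <- "paper"
  cfg$scene$height <- 512; cfg$scene$width <- 512
  cfg$data <- list(n_total = 2000, labelled_fraction = 0.1)
  cfg$model <- list(depth = 6, base_channels = 16, seed = 1)
  cfg$train$epochs <- 1000; cfg$train$batch_size <- 64
  cfg$adversarial$steps <- 25
  cfg$loss$rampup_epochs <- 300
  cfg$metrics$tolerance <- 13
  cfg
}

check_known_keys <- function(user, ref, path = "") {
  for (nm in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(ref))
      stop("unknown configuration key: ", here, call. = FALSE)
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop("configuration key ", here, " must be a section", call. = FALSE)
      check_known_keys(user[[nm]], ref[[nm]], here)
    }
  }
  invisible(TRUE)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]])) &&
        is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

validate_run_config <- function(cfg) {
  # constructors carry the invariant checks; they throw naming the offence
  sc <- do.call(scene_config, cfg$scene)
  do.call(model_config, c(cfg$model, list(n_classes = sc$n_classes)))
  do.call(train_config,
          c(cfg$train, list(adversarial = cfg$adversarial, loss = cfg$loss)))
  stopifnot_config(cfg$data$n_total >= 1, "data.n_total must be >= 1")
  stopifnot_config(cfg$data$labelled_fraction > 0 &&
                     cfg$data$labelled_fraction <= 1,
                   "data.labelled_fraction must lie in (0, 1]")
  invisible(cfg)
}

#' Load a run configuration
#'
#' Reads a YAML document, fills unspecified keys from the named profile
#' (`profile:` key in the file, `desk` by default), rejects unknown keys
#' naming the offending path, and validates every invariant through the
#' section constructors.
#'
#' @param path YAML file path, or `NULL` for pure profile defaults.
#' @param profile fallback profile name when the file does not set one.
#' @return Fully-resolved configuration list.
#' @export
load_config <- function(path = NULL, profile = "desk") {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  prof_name <- if (!is.null(user$profile)) user$profile else profile
  base <- switch(prof_name, desk = desk_profile(), paper = paper_profile(),
                 stop("unknown profile: ", prof_name, call. = FALSE))
  check_known_keys(user, base)
  cfg <- merge_config(base, user)
  cfg$profile <- prof_name
  validate_run_config(cfg)
  cfg
}

#' Save a resolved configuration
#'
#' @param cfg configuration list.
#' @param path output YAML path.
#' @return Invisibly, `path`.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# ---- dataset folder I/O ---------------------------------------------------

#' Write a generated dataset to a folder
#'
#' Writes `images/NNNN.png` (8-bit RGB), `masks/NNNN.png` (8-bit single
#' channel, pixel value = class id; only for labelled scenes) and
#' `split.json` listing the labelled/unlabelled indices.
#'
#' @param dataset a `seg_dataset` from [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  nm <- function(i) sprintf("%04d.png", i)
  for (k in seq_along(dataset$labelled)) {
    i <- dataset$labelled_idx[k]
    png::writePNG(dataset$labelled[[k]]$image, file.path(dir, "images", nm(i)))
    png::writePNG(dataset$labelled[[k]]$mask / 255,
                  file.path(dir, "masks", nm(i)))
  }
  for (k in seq_along(dataset$unlabelled)) {
    i <- dataset$unlabelled_idx[k]
    png::writePNG(dataset$unlabelled[[k]], file.path(dir, "images", nm(i)))
  }
  jsonlite::write_json(list(labelled = dataset$labelled_idx,
                            unlabelled = dataset$unlabelled_idx,
                            n_classes = dataset$n_classes),
                       file.path(dir, "split.json"))
  invisible(dir)
}

read_png_image <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2) x <- array(rep(x, 3), c(dim(x), 3))
  if (dim(x)[3] == 4) x <- x[, , 1:3]
  x
}

read_png_mask <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
}

#' Read an image/mask folder
#'
#' Expects `images/`; `masks/` is optional per image (missing mask = the
#' image is unlabelled). Pairing is by filename stem in stable lexicographic
#' order. Images are scaled to [0,1]; masks are integer class ids.
#'
#' @param dir dataset directory.
#' @param n_classes class count; when `NULL`, taken from `split.json` if
#'   present, else `max(mask) + 1`.
#' @return A `seg_dataset`.
#' @export
read_mask_folder <- function(dir, n_classes = NULL) {
  imgs <- sort(list.files(file.path(dir, "images"), pattern = "\\.png$"))
  stopifnot_config(length(imgs) > 0, "no images found")
  labelled <- list(); unlabelled <- list()
  lab_idx <- integer(0); unlab_idx <- integer(0)
  max_cls <- 0L
  for (k in seq_along(imgs)) {
    img <- read_png_image(file.path(dir, "images", imgs[k]))
    mpath <- file.path(dir, "masks", imgs[k])
    if (file.exists(mpath)) {
      mask <- read_png_mask(mpath)
      if (!all(dim(mask) == dim(img)[1:2]))
        stop("mask/image size mismatch for ", imgs[k], call. = FALSE)
      labelled[[length(labelled) + 1]] <- list(image = img, mask = mask)
      lab_idx <- c(lab_idx, k)
      max_cls <- max(max_cls, max(mask))
    } else {
      unlabelled[[length(unlabelled) + 1]] <- img
      unlab_idx <- c(unlab_idx, k)
    }
  }
  if (is.null(n_classes)) {
    sp <- file.path(dir, "split.json")
    n_classes <- if (file.exists(sp)) jsonlite::fromJSON(sp)$n_classes
      else max_cls + 1L
  }
  structure(list(labelled = labelled, unlabelled = unlabelled,
                 n_classes = as.integer(n_classes),
                 labelled_idx = lab_idx, unlabelled_idx = unlab_idx),
            class = "seg_dataset")
}

#' Evaluate prediction masks against ground-truth masks on disk
#'
#' @param pred_dir,gt_dir folders of single-channel class-id PNG masks with
#'   matching filenames.
#' @param tau NSD tolerance in pixels.
#' @param n_classes class count L.
#' @return A `metric_report`-style list.
#' @export
evaluate_folders <- function(pred_dir, gt_dir, tau, n_classes) {
  files <- sort(list.files(gt_dir, pattern = "\\.png$"))
  preds <- lapply(files, function(f) read_png_mask(file.path(pred_dir, f)))
  gts <- lapply(files, function(f) read_png_mask(file.path(gt_dir, f)))
  fg <- seq_len(n_classes - 1L)
  dice_img <- mapply(function(p, g) {
    cls <- fg[fg %in% g | fg %in% p]
    if (length(cls) == 0) return(1)
    mean(vapply(cls, function(c) dice_score(p, g, c), numeric(1)))
  }, preds, gts)
  nsd_img <- mapply(function(p, g) nsd_score(p, g, tau), preds, gts)
  iou <- multiclass_iou_report(preds, gts, n_classes)
  list(dice = mean(dice_img), nsd = mean(nsd_img), tolerance = tau,
       ch_iou = iou$ch_iou, isi_iou = iou$isi_iou, mc_iou = iou$mc_iou,
       per_class_iou = iou$per_class)
}
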