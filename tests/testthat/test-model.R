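test_that("model construction is seeded and shape-preserving", {
  m1 <- tiny_model(n_classes = 3, seed = 42)
  m2 <- tiny_model(n_classes = 3, seed = 42)
  expect_identical(m1$params, m2$params)
  m3 <- tiny_model(n_classes = 3, seed = 43)
  expect_false(identical(m1$params, m3$params))

  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  lg <- forward(m1, x)
  expect_equal(dim(lg), c(16, 16, 3))
  expect_true(all(is.finite(lg)))
  expect_true(all(is.finite(forward(m1, array(0, c(16, 16, 3))))))
  expect_true(all(is.finite(forward(m1, array(1, c(16, 16, 3))))))

  expect_error(forward(m1, array(0.5, c(18, 18, 3))), "multiple of")
  expect_error(forward(m1, array(NA_real_, c(16, 16, 3))), "non-finite")
  expect_error(model_config(depth = 0), "depth")
  expect_error(model_config(n_classes = 1), "n_classes")
})

test_that("inference is deterministic and batch-consistent", {
  m <- tiny_model(seed = 1)
  set.seed(2)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  X <- array(c(x, x), c(16, 16, 3, 2))
  out <- segmatch:::model_forward(m, X)
  expect_identical(out[, , , 1], out[, , , 2])

  set.seed(3)
  B <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  B2 <- array(c(B, B), c(16, 16, 3, 4))
  o1 <- segmatch:::model_forward(m, B)
  o2 <- segmatch:::model_forward(m, B2)
  expect_equal(o1, o2[, , , 1:2, drop = FALSE], ignore_attr = TRUE)
})

test_that("hand-written gradients match finite differences", {
  set.seed(7)
  m <- tiny_model(n_classes = 3, seed = 7)
  # non-trivial running statistics so evaluation mode is exercised honestly
  m$stats <- lapply(m$stats, function(st)
    list(mean = st$mean + rnorm(length(st$mean), sd = 0.1),
         var = st$var * runif(length(st$var), 0.5, 2)))
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  y <- matrix(sample(0:2, 256, TRUE), 16, 16)
  lossf <- function(model, xx)
    segmatch:::sup_loss_one(forward(model, xx), y)$loss

  fc <- segmatch:::model_forward(m, x, want_cache = TRUE)
  r <- segmatch:::sup_loss_one(array(fc$logits, dim(fc$logits)[1:3]), y,
                               want_grad = TRUE)
  bk <- segmatch:::model_backward(m, fc$caches, r$dlogits)
  eps <- 1e-5
  for (nm in c("stem_W", "down1_W", "res1a_W", "res2b_g", "up1_W", "fuse2_e",
               "head_W", "head_b")) {
    for (i in sample(length(m$params[[nm]]), 2)) {
      mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
      num <- (lossf(mp, x) - lossf(mm, x)) / (2 * eps)
      expect_equal(bk$grads[[nm]][i], num, tolerance = 1e-5, info = nm)
    }
  }
  gi <- input_gradient(m, x, r$dlogits)
  for (i in sample(length(x), 4)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    num <- (lossf(m, xp) - lossf(m, xm)) / (2 * eps)
    expect_equal(gi[i], num, tolerance = 1e-5)
  }
  # connectivity: every parameter tensor receives some gradient
  expect_true(all(vapply(bk$grads, function(g) any(g != 0), logical(1))))

  # training mode (batch statistics) on a 2-image batch
  X <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  Y <- list(y, matrix(sample(0:2, 256, TRUE), 16, 16))
  loss_tr <- function(model, XX) {
    lg <- segmatch:::model_forward(model, XX, training = TRUE)$logits
    mean(vapply(1:2, function(i)
      segmatch:::sup_loss_one(array(lg[, , , i], dim(lg)[1:3]),
                              Y[[i]])$loss, numeric(1)))
  }
  ft <- segmatch:::model_forward(m, X, want_cache = TRUE, training = TRUE)
  dlt <- array(0, dim(ft$logits))
  for (i in 1:2) {
    rt <- segmatch:::sup_loss_one(array(ft$logits[, , , i], dim(ft$logits)[1:3]),
                                  Y[[i]], want_grad = TRUE)
    dlt[, , , i] <- rt$dlogits / 2
  }
  bkt <- segmatch:::model_backward(m, ft$caches, dlt)
  for (nm in c("stem_W", "res2a_g", "fuse1_W", "down1_g")) {
    for (i in sample(length(m$params[[nm]]), 2)) {
      mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mm2 <- m; mm2$params[[nm]][i] <- mm2$params[[nm]][i] - eps
      num <- (loss_tr(mp, X) - loss_tr(mm2, X)) / (2 * eps)
      expect_equal(bkt$grads[[nm]][i], num, tolerance = 1e-4, info = nm)
    }
  }
})

test_that("the backbone can overfit a single scene", {
  sc <- tiny_scene_config(seed = 21)
  scene <- generate_scene(sc, 1)
  m <- build_model(model_config(depth = 2, base_channels = 8, n_classes = 2,
                                seed = 5))
  opt <- segmatch:::zero_like(m$params)
  for (step in 1:200) {
    fc <- segmatch:::model_forward(m, scene$image, want_cache = TRUE,
                                   training = TRUE)
    m$stats <- fc$stats
    r <- segmatch:::sup_loss_one(array(fc$logits, dim(fc$logits)[1:3]),
                                 scene$mask, want_grad = TRUE)
    bk <- segmatch:::model_backward(m, fc$caches, r$dlogits)
    upd <- segmatch:::sgd_update(m, opt, bk$grads, lr = 0.02, momentum = 0.9)
    m <- upd$model; opt <- upd$opt
  }
  expect_gt(dice_score(predict_mask(m, scene$image), scene$mask, 1), 0.99)
})

test_that("checkpoints round-trip through JSON", {
  m <- tiny_model(seed = 9)
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(m2$cfg, m$cfg)
  expect_equal(m2$params, m$params)
  expect_equal(m2$stats, m$stats)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_equal(forward(m2, x), forward(m, x))
})
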