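test_that("transform sampling honours the enabled set and the seed", {
  set.seed(1)
  for (i in 1:20)
    expect_equal(sample_weak_transform(c(32, 32), enabled = "hflip")$kind,
                 "hflip")
  set.seed(9)
  d1 <- replicate(50, sample_weak_transform(c(32, 32))$kind)
  set.seed(9)
  d2 <- replicate(50, sample_weak_transform(c(32, 32))$kind)
  expect_identical(d1, d2)
  expect_error(sample_weak_transform(c(32, 32), enabled = character(0)),
               "empty")
  expect_error(sample_weak_transform(c(8, 8)), ">= 16")
})

test_that("dihedral draw frequencies are near uniform", {
  set.seed(4)
  kinds <- setdiff(DIHEDRAL_KINDS, character(0))
  d <- replicate(10000, sample_weak_transform(c(32, 32), enabled = kinds)$kind)
  counts <- table(factor(d, levels = kinds))
  expected <- 10000 / length(kinds)
  sd5 <- 5 * sqrt(10000 * (1 / 6) * (5 / 6))
  expect_true(all(abs(counts - expected) <= sd5))
})

test_that("dihedral transforms permute pixels and invert exactly", {
  set.seed(2)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  for (k in DIHEDRAL_KINDS) {
    t <- segmatch:::weak_transform(k)
    y <- apply_weak(t, x)
    expect_equal(sort(as.vector(y)), sort(as.vector(x)))
    inv <- invert_on_logits(t, y, c(16, 16))
    expect_identical(inv$logits, x)
    expect_true(all(inv$valid))
  }
  # hflip of a column ramp reverses the ramp
  ramp <- array(rep(1:8, each = 8), c(8, 8, 1))
  flipped <- apply_weak(segmatch:::weak_transform("hflip"), ramp)
  expect_equal(flipped[1, , 1], 8:1)
  # rot90 applied four times is the identity
  r <- x
  for (i in 1:4) r <- apply_weak(segmatch:::weak_transform("rot90"), r)
  expect_identical(r, x)
})

test_that("vflip on a 2x2 logit map is an involution", {
  lg <- array(c(1, 3, 2, 4), c(2, 2, 1))
  t <- segmatch:::weak_transform("vflip")
  inv <- invert_on_logits(t, apply_weak(t, lg), c(2, 2))
  expect_identical(inv$logits, lg)
})

test_that("crop_resize agrees with direct index arithmetic on a 4x4 grid", {
  # full-image rectangle: resize is the identity at matching sizes
  g <- array(matrix(1:16, 4, 4), c(4, 4, 1))
  t_full <- segmatch:::weak_transform("crop_resize",
                                      list(y0 = 0, x0 = 0, ch = 4, cw = 4))
  expect_equal(apply_weak(t_full, g), g)

  # 2x2 rectangle upsampled to 4x4: hand-computed bilinear values with the
  # half-pixel convention; source coords for n=2 -> 4 are (0, .5, 1, 1)+1
  t2 <- segmatch:::weak_transform("crop_resize",
                                  list(y0 = 1, x0 = 2, ch = 2, cw = 2))
  a <- g[2, 3, 1]; b <- g[3, 3, 1]; cc <- g[2, 4, 1]; dd <- g[3, 4, 1]
  # half-pixel source coords for 2 -> 4: (i - 0.5)/2 - 0.5, clamped
  wy <- c(0, 0.25, 0.75, 1); wx <- c(0, 0.25, 0.75, 1)
  expected <- outer(seq_along(wy), seq_along(wx), function(i, j)
    (1 - wy[i]) * (1 - wx[j]) * a + wy[i] * (1 - wx[j]) * b +
      (1 - wy[i]) * wx[j] * cc + wy[i] * wx[j] * dd)
  expect_equal(apply_weak(t2, g)[, , 1], expected)
})

test_that("crop_resize inversion restricts validity to the rectangle", {
  set.seed(3)
  lg <- array(runif(16 * 16 * 2), c(16, 16, 2))
  t <- segmatch:::weak_transform("crop_resize",
                                 list(y0 = 2, x0 = 5, ch = 9, cw = 8))
  out <- invert_on_logits(t, lg, c(16, 16))
  expect_equal(sum(out$valid), 9 * 8)
  expect_true(all(out$valid[3:11, 6:13]))
  expect_true(all(out$logits[!out$valid] == 0))
  expect_error(apply_weak(segmatch:::weak_transform(
    "crop_resize", list(y0 = 10, x0 = 0, ch = 9, cw = 8)),
    array(0, c(16, 16, 1))), "bounds")
})

test_that("identity transform is a no-op with full validity", {
  lg <- array(rnorm(32), c(4, 4, 2))
  out <- invert_on_logits(segmatch:::weak_transform("identity"), lg, c(4, 4))
  expect_identical(out$logits, lg)
  expect_true(all(out$valid))
})

test_that("a pixel-wise operator is recovered exactly through the round trip", {
  # f acts per pixel, so it commutes with any spatial permutation:
  # invert(f(apply(x))) must equal f(x) exactly on valid pixels
  f <- function(x) x^2 + 0.5 * x
  set.seed(8)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  for (k in c(DIHEDRAL_KINDS, "crop_resize")) {
    t <- if (k == "crop_resize")
      segmatch:::weak_transform(k, list(y0 = 3, x0 = 1, ch = 10, cw = 12))
    else segmatch:::weak_transform(k)
    out <- invert_on_logits(t, f(apply_weak(t, x)), c(16, 16))
    ref <- f(x)
    if (k %in% DIHEDRAL_KINDS) {
      expect_identical(out$logits, ref)
    } else {
      # resampling is not exactly invertible; just require validity marking
      expect_equal(sum(out$valid), 10 * 12)
    }
  }
})

test_that("transforms serialize to JSON and back", {
  t <- segmatch:::weak_transform("crop_resize",
                                 list(y0 = 1, x0 = 2, ch = 8, cw = 9))
  t2 <- weak_from_json(weak_to_json(t))
  expect_equal(t2$kind, t$kind)
  expect_equal(t2$params, t$params)
})
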