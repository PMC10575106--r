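# loss functions: bottleneck alignment, cross-entropy, dice variants,
# Tversky, and their combinations

test_that("alignment loss matches hand-computed and boundary cases", {
  # identical binary maps saturate the Cauchy-Schwarz bound
  y <- matrix(0, 8, 8); y[c(3, 10, 40)] <- 1
  expect_equal(loss_mid(y, y), -1, tolerance = 1e-12)

  # disjoint supports give exactly zero
  x <- matrix(0, 8, 8); x[c(1, 2)] <- 5
  expect_identical(loss_mid(x, y), 0)

  # 2x2 worked case: -1/sqrt(2)
  expect_equal(loss_mid(diag(2), matrix(c(1, 0, 0, 0), 2, 2)),
               -1 / sqrt(2), tolerance = 1e-9)

  # all-zero map warns and returns 0
  expect_warning(v <- loss_mid(matrix(0, 8, 8), y), "all-zero")
  expect_identical(v, 0)
  expect_error(loss_mid(matrix(-1, 2, 2), matrix(1, 2, 2)), "nonnegative")
  expect_error(loss_mid(matrix(1, 2, 2), matrix(1, 3, 3)), "shapes")
})

test_that("alignment loss is bounded, proportional-saturating and scale
           invariant on random nonnegative maps", {
  set.seed(42)
  for (i in 1:300) {
    x <- matrix(rexp(64), 8, 8)
    y <- matrix(rbinom(64, 1, 0.2), 8, 8)
    if (sum(y) == 0) y[1] <- 1
    v <- loss_mid(x, y)
    expect_gte(v, -1); expect_lte(v, 0)
    expect_equal(loss_mid(2.5 * x, y), v, tolerance = 1e-12)
    expect_equal(loss_mid(x, y * 1), loss_mid(x, y), tolerance = 0)
    expect_equal(loss_mid(3 * y, y), -1, tolerance = 1e-12)
  }
})

test_that("cross-entropy matches direct evaluation and is monotone", {
  m <- matrix(c(1, 0, 0, 1), 2, 2)
  hot <- one_hot(m)
  expect_equal(loss_ce(hot, hot), 0, tolerance = 1e-5)

  # single pixel at probability 0.5 on the true class
  x <- array(0.5, dim = c(1, 1, 2))
  y <- array(c(0, 1), dim = c(1, 1, 2))
  expect_equal(loss_ce(x, y), -log(0.5), tolerance = 1e-9)

  probs <- seq(0.9, 0.1, by = -0.2)
  losses <- vapply(probs, function(p) {
    x <- array(c(1 - p, p), dim = c(1, 1, 2))
    loss_ce(x, y)
  }, numeric(1))
  expect_true(all(diff(losses) > 0))
  expect_error(loss_ce(x, one_hot(m)), "mismatch")

  # mean reduction divides by the pixel count
  x4 <- array(0.5, dim = c(2, 2, 2))
  y4 <- one_hot(matrix(c(1, 0, 0, 1), 2, 2))
  expect_equal(loss_ce(x4, y4, "mean"), loss_ce(x4, y4) / 4)
})

test_that("dice variants match their closed forms", {
  cfg_p <- loss_config(dice_variant = "as_printed")
  cfg_s <- loss_config(dice_variant = "standard")

  # one-class single active pixel, printed variant: 1 - 1/(1 + 1e-5)
  x1 <- array(1, dim = c(1, 1, 1))
  expect_equal(loss_dice(x1, x1, cfg_p), 1 - 1 / (1 + 1e-5),
               tolerance = 1e-12)

  # standard variant at perfect two-class overlap: each class term -> 1
  m <- matrix(c(1, 0, 0, 1), 2, 2)
  hot <- one_hot(m)
  expect_equal(loss_dice(hot, hot, cfg_s), -1, tolerance = 1e-4)

  # disjoint maps: both class terms vanish
  a <- matrix(c(1, 0, 0, 0), 2, 2)
  b <- matrix(c(0, 0, 0, 1), 2, 2)
  xa <- array(a, dim = c(2, 2, 1)); xb <- array(b, dim = c(2, 2, 1))
  expect_equal(loss_dice(xa, xb, cfg_p), 1, tolerance = 1e-5)
})

test_that("Tversky at alpha = beta = 0.5 is the smoothed dice loss", {
  m <- matrix(c(1, 0, 0, 1), 2, 2)
  hot <- one_hot(m)
  expect_equal(loss_tversky(hot, hot), 0, tolerance = 1e-5)

  a <- one_hot(matrix(c(1, 0, 0, 0), 2, 2))[, , 2, drop = FALSE]
  b <- one_hot(matrix(c(0, 0, 0, 1), 2, 2))[, , 2, drop = FALSE]
  expect_equal(loss_tversky(a, b), 1, tolerance = 1e-4)

  set.seed(7)
  for (i in 1:100) {
    x <- array(runif(32), dim = c(4, 4, 2))
    y <- one_hot(matrix(rbinom(16, 1, 0.4), 4, 4))
    expect_equal(loss_tversky(x, y, 0.5, 0.5), smoothed_dice_loss(x, y),
                 tolerance = 1e-9)
  }
})

test_that("combined objectives decompose into their terms", {
  set.seed(3)
  x <- array(runif(32, 0.01, 0.99), dim = c(4, 4, 2))
  y <- one_hot(matrix(rbinom(16, 1, 0.4), 4, 4))
  xm <- matrix(rexp(4), 2, 2); ym <- matrix(c(1, 0, 0, 1), 2, 2)

  for (comb in c("tversky_ce", "tversky_ce_mid", "eq_sum")) {
    cfg <- loss_config(combination = comb)
    r <- loss_combined(xm, x, ym, y, cfg)
    expect_equal(sum(r$terms), r$total)
  }

  cfg <- loss_config(combination = "tversky_ce")
  r <- loss_combined(xm, x, ym, y, cfg)
  expect_identical(r$terms[["tversky"]], loss_tversky(x, y, 0.5, 0.5))
  expect_identical(r$terms[["ce"]], loss_ce(x, y))

  # perfect prediction under the multi-loss objective: -1 + 0 + 0
  hot <- one_hot(matrix(c(1, 0, 0, 1), 2, 2))
  r2 <- loss_combined(ym, hot, ym, hot,
                      loss_config(combination = "tversky_ce_mid"))
  expect_equal(r2$total, -1, tolerance = 1e-4)
})

test_that("losses are invariant under a common pixel permutation", {
  set.seed(11)
  x <- array(runif(50, 0.01, 0.99), dim = c(5, 5, 2))
  y <- one_hot(matrix(rbinom(25, 1, 0.3), 5, 5))
  perm <- sample(25)
  px <- array(c(matrix(x[, , 1], 25)[perm], matrix(x[, , 2], 25)[perm]),
              dim = c(5, 5, 2))
  py <- array(c(matrix(y[, , 1], 25)[perm], matrix(y[, , 2], 25)[perm]),
              dim = c(5, 5, 2))
  expect_equal(loss_ce(px, py), loss_ce(x, y), tolerance = 1e-12)
  expect_equal(loss_dice(px, py), loss_dice(x, y), tolerance = 1e-12)
  expect_equal(loss_tversky(px, py), loss_tversky(x, y), tolerance = 1e-12)
})
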