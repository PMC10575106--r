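# hybrid counting rule and its ablation modes

# build a mask with discs at given polar positions around a center
disc_mask_at <- function(h, w, centers, rad = 4) {
  m <- matrix(0L, h, w)
  for (i in seq_len(nrow(centers))) {
    d <- sqrt(outer((seq_len(h) - centers[i, 1])^2,
                    (seq_len(w) - centers[i, 2])^2, `+`))
    m[d <= rad] <- 1L
  }
  m
}

# a circular localization centered in an h x w frame
manual_localization <- function(h, w, r1, r3) {
  d <- sqrt(outer((seq_len(h) - h / 2)^2, (seq_len(w) - w / 2)^2, `+`))
  bez <- matrix(0L, h, w)
  bez[d > r3 & d <= r1] <- 1L
  structure(list(c1 = circle(w / 2, h / 2, r1), c2 = NULL,
                 c3 = circle(w / 2, h / 2, r3), bezel_mask = bez,
                 found = TRUE), class = "dish_localization")
}

test_that("hybrid arithmetic: inner + bezel/2, fallback returns naive", {
  h <- w <- 200
  loc <- manual_localization(h, w, r1 = 90, r3 = 70)
  set.seed(2)
  th_in <- seq(0, 2 * pi, length.out = 11)[1:10]
  inner_centers <- cbind(h / 2 + 40 * sin(th_in), w / 2 + 40 * cos(th_in))
  th_bz <- seq(0.2, 2 * pi, length.out = 5)[1:4]
  bezel_centers <- cbind(h / 2 + 80 * sin(th_bz), w / 2 + 80 * cos(th_bz))
  mask <- disc_mask_at(h, w, rbind(inner_centers, bezel_centers))

  r <- hybrid_count(mask, loc, "hybrid")
  expect_equal(r$inner_count, 10)
  expect_equal(r$bezel_count, 4)
  expect_equal(r$n_hybrid, 12)
  expect_equal(r$n, 12)
  expect_equal(r$n_uniform, 14)
  expect_equal(r$n_naive, 14)
  expect_false(r$used_fallback)
  # halving identity holds exactly
  expect_equal(r$n_hybrid - r$inner_count, r$bezel_count / 2)

  fl <- failed_localization(h, w)
  rf <- hybrid_count(mask, fl, "hybrid")
  expect_true(rf$used_fallback)
  expect_equal(rf$n, rf$n_naive)
  expect_equal(rf$n_naive, 14)
})

test_that("regions wholly outside the dish are discarded and straddling
           regions are assigned atomically", {
  h <- w <- 200
  loc <- manual_localization(h, w, r1 = 70, r3 = 50)
  mask <- disc_mask_at(h, w, rbind(c(100, 100),   # inner
                                   c(100, 160),   # bezel (d = 60)
                                   c(20, 20)))    # off-dish
  r <- hybrid_count(mask, loc)
  expect_equal(r$inner_count, 1)
  expect_equal(r$bezel_count, 1)
  expect_equal(r$n_naive, 3)
  expect_equal(r$n_hybrid, 1.5)

  # a region centered on the C3 boundary is one region, not two
  strad <- disc_mask_at(h, w, cbind(100, 150), rad = 6)  # d = 50
  ra <- hybrid_count(strad, loc, assignment = "region")
  expect_equal(ra$inner_count + ra$bezel_count, 1)
  rp <- hybrid_count(strad, loc, assignment = "pixelwise")
  expect_equal(rp$inner_count + rp$bezel_count, 2)
})

test_that("ablation modes agree with each other and with direct calls", {
  sc <- generate_scene(tiny_gen(reflection_prob = 1), seed = 10)
  loc <- truth_localization(sc)
  mask <- sc$visible_mask
  ab <- ablation_count(mask, loc)
  expect_identical(ab$hybrid, hybrid_count(mask, loc, "hybrid"))
  expect_equal(ab$uniform$n, ab$uniform$n_uniform)
  expect_equal(ab$naive$n, ab$naive$n_naive)
  expect_gte(ab$uniform$n, ab$hybrid$n)

  # without bezel regions all three modes coincide
  sc0 <- generate_scene(tiny_gen(bezel_colony_frac = 0,
                                 reflection_prob = 0), seed = 10)
  ab0 <- ablation_count(sc0$truth_mask, truth_localization(sc0))
  expect_equal(ab0$naive$n, ab0$uniform$n)
  expect_equal(ab0$uniform$n, ab0$hybrid$n)
})

test_that("with reflection twins the hybrid count beats naive counting on
           ground-truth visible masks", {
  errs <- matrix(NA_real_, 20, 2)
  for (s in 1:20) {
    sc <- generate_scene(tiny_gen(reflection_prob = 1), seed = 300 + s)
    loc <- truth_localization(sc)
    r <- hybrid_count(sc$visible_mask, loc, "hybrid")
    errs[s, ] <- c(abs(r$n_hybrid - sc$true_count),
                   abs(r$n_naive - sc$true_count))
  }
  expect_lte(mean(errs[, 1]), mean(errs[, 2]))
})

test_that("shape mismatches and bad inputs error", {
  loc <- manual_localization(64, 64, 25, 18)
  expect_error(hybrid_count(matrix(0L, 32, 32), loc), "differ")
  expect_error(hybrid_count(matrix(0L, 64, 64), list()), "dish_localization")
})
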