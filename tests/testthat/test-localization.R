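# dish localization: blur, Canny, circle Hough, and the C1/C2/C3 cascade

test_that("Gaussian kernel and blur behave like a unit-mass smoother", {
  k <- gaussian_kernel(1, normalize = FALSE)
  expect_equal(k[4, 4], 1 / (2 * pi), tolerance = 1e-12)
  expect_equal(sum(gaussian_kernel(2)), 1, tolerance = 1e-12)
  expect_error(gaussian_kernel(-1), "sigma")
  expect_error(gaussian_blur(matrix(0, 4, 4), blur_config(0)), "sigma")

  const <- matrix(0.42, 40, 40)
  expect_lt(max(abs(gaussian_blur(const) - 0.42)), 1e-10)

  # total intensity conserved for interior-supported content
  m <- matrix(0, 64, 64); m[30:34, 30:34] <- 1
  expect_equal(sum(gaussian_blur(m, blur_config(2))), sum(m),
               tolerance = 1e-6)
})

test_that("Canny finds a ring on a disc and nothing on a constant", {
  expect_equal(sum(detect_edges(matrix(0.5, 64, 64))), 0)

  d <- sqrt(outer((1:120 - 60)^2, (1:120 - 55)^2, `+`))
  disc <- matrix(as.numeric(d <= 30), 120, 120)
  e <- detect_edges(gaussian_blur(disc, blur_config(1.5)))
  expect_true(all(e %in% c(0L, 1L)))
  expect_gt(sum(e), 50)
  ed <- d[e == 1]
  expect_true(all(abs(ed - 30) <= 2))
  expect_error(detect_edges(disc, low = 0.5, high = 0.2), "below")
})

test_that("cone-voting Hough recovers circles and matches the exhaustive
           accumulator argmax", {
  e <- raster_circle_edges(120, 120, y0 = 60, x0 = 50, r = 20)
  pk <- hough_circles(e, c(12, 30), top_k = 1)
  expect_length(pk, 1)
  expect_lt(abs(pk[[1]]$circle$x0 - 50), 1)
  expect_lt(abs(pk[[1]]$circle$y0 - 60), 1)
  expect_lt(abs(pk[[1]]$circle$r - 20), 1)

  expect_identical(hough_circles(matrix(0L, 32, 32), c(5, 10)), list())

  # two concentric circles both recovered in the top 2
  e2 <- raster_circle_edges(140, 140, 70, 70, 20) |
    raster_circle_edges(140, 140, 70, 70, 40)
  pk2 <- hough_circles(e2 + 0L, c(12, 48), top_k = 2)
  radii <- sort(vapply(pk2, function(p) p$circle$r, numeric(1)))
  expect_equal(radii, c(20, 40), tolerance = 1.5)

  # argmax agreement with the brute-force oracle on small instances
  set.seed(31)
  for (i in 1:5) {
    y0 <- runif(1, 25, 39); x0 <- runif(1, 25, 39); r <- runif(1, 10, 10)
    e3 <- raster_circle_edges(64, 64, y0, x0, round(r))
    hh <- hough_circles(e3, c(6, 14), top_k = 1, return_votes = TRUE)
    oracle <- brute_force_hough_argmax(e3, c(6, 14))
    mine <- which(hh$votes == max(hh$votes), arr.ind = TRUE)[1, ]
    expect_true(all(abs(as.integer(mine) - oracle$bin) <= 1))
  }
})

test_that("gradient-voting Hough agrees with cone voting on a clean
           circle", {
  d <- sqrt(outer((1:120 - 62)^2, (1:120 - 58)^2, `+`))
  disc <- matrix(as.numeric(d <= 25), 120, 120)
  ce <- cfuhybrid:::canny_edges(gaussian_blur(disc, blur_config(1.5)))
  pk_c <- hough_circles(ce$edges, c(15, 35), top_k = 1, method = "cone")
  pk_g <- hough_circles(ce$edges, c(15, 35), top_k = 1,
                        method = "gradient", gx = ce$gx, gy = ce$gy)
  expect_lt(abs(pk_c[[1]]$circle$r - pk_g[[1]]$circle$r), 2)
  expect_lt(abs(pk_c[[1]]$circle$x0 - pk_g[[1]]$circle$x0), 2)
})

test_that("the cascade recovers dish, glass and water edges on scenes", {
  for (s in c(2, 9)) {
    sc <- generate_scene(tiny_gen(), seed = s)
    loc <- localize_dish(sc$image)
    expect_true(loc$found)
    expect_lt(abs(loc$c1$r - sc$dish$r), 2.5)
    expect_lt(abs(loc$c3$r - sc$water$r), max(2.5, sc$glass$r - sc$water$r))
    area <- pi * (loc$c1$r^2 - loc$c3$r^2)
    expect_lt(abs(sum(loc$bezel_mask) / area - 1), 0.05)
    # bezel excludes the interior of the water circle
    d <- sqrt(outer((1:256 - loc$c1$y0)^2, (1:256 - loc$c1$x0)^2, `+`))
    expect_equal(sum(loc$bezel_mask[d <= loc$c3$r]), 0)
  }
})

test_that("blank images yield found = FALSE with an empty mask", {
  blank <- array(0.3, dim = c(128, 128, 3))
  loc <- localize_dish(blank)
  expect_false(loc$found)
  expect_equal(sum(loc$bezel_mask), 0)
})

test_that("localization commutes with a quarter-turn rotation", {
  sc <- generate_scene(tiny_gen(), seed = 13)
  loc <- localize_dish(sc$image)
  rot <- array(0, dim = dim(sc$image))
  h <- dim(sc$image)[1]
  for (ch in 1:3) rot[, , ch] <- t(sc$image[, , ch])[, h:1]
  loc_r <- localize_dish(rot)
  expect_true(loc$found && loc_r$found)
  expect_lt(abs(loc$c1$r - loc_r$c1$r), 2)
  # rotated center maps onto the original under the inverse rotation
  expect_lt(abs(loc_r$c1$x0 - (h + 1 - loc$c1$y0)), 2.5)
  expect_lt(abs(loc_r$c1$y0 - loc$c1$x0), 2.5)
})
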