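# synthetic scene generator: determinism, geometry invariants, masks,
# annotation round trips

test_that("generation is deterministic and satisfies type invariants", {
  cfg <- tiny_gen()
  sc1 <- generate_scene(cfg, seed = 11)
  sc2 <- generate_scene(cfg, seed = 11)
  expect_identical(sc1, sc2)

  expect_lt(sc1$water$r, sc1$glass$r)
  expect_lt(sc1$glass$r, sc1$dish$r)
  expect_lt(abs(sc1$glass$x0 - sc1$dish$x0), 2)
  expect_lt(abs(sc1$water$y0 - sc1$dish$y0), 2)
  expect_equal(sc1$true_count, nrow(sc1$colonies))
  expect_true(all(sc1$truth_mask <= sc1$visible_mask))
  expect_true(all(dim(sc1$image) == c(256, 256, 3)))
  expect_true(min(sc1$image) >= 0 && max(sc1$image) <= 1)
})

test_that("empty scene and reflection-free scene behave as stated", {
  sc0 <- generate_scene(tiny_gen(count_range = 0L), seed = 1)
  expect_equal(sc0$true_count, 0)
  expect_true(all(sc0$truth_mask == 0))

  sc5 <- generate_scene(tiny_gen(count_range = 5L, reflection_prob = 0),
                        seed = 7)
  expect_equal(sc5$true_count, 5)
  expect_identical(sc5$visible_mask, sc5$truth_mask)
  expect_equal(nrow(sc5$reflections), 0)
})

test_that("reflections land strictly inside the bezel annulus and add
           regions to the visible mask", {
  found_some <- FALSE
  for (s in 1:8) {
    sc <- generate_scene(tiny_gen(reflection_prob = 1), seed = s)
    if (nrow(sc$reflections) == 0) next
    found_some <- TRUE
    refl_px <- which(sc$visible_mask == 1 & sc$truth_mask == 0)
    h <- 256
    rr <- (refl_px - 1) %% h + 1; cc <- (refl_px - 1) %/% h + 1
    d_dish <- sqrt((rr - sc$dish$y0)^2 + (cc - sc$dish$x0)^2)
    d_water <- sqrt((rr - sc$water$y0)^2 + (cc - sc$water$x0)^2)
    expect_true(all(d_water > sc$water$r))
    expect_true(all(d_dish < sc$dish$r))
    # every reflection is linked to an existing parent colony
    expect_true(all(sc$reflections$parent_id %in% sc$colonies$id))
    # naive count on the visible mask sees colonies plus reflections
    expect_equal(flood_fill_count(sc$visible_mask),
                 sc$true_count + nrow(sc$reflections))
  }
  expect_true(found_some)
})

test_that("connected-component count of the truth mask equals the true
           count under non-overlap", {
  for (s in c(3, 21)) {
    sc <- generate_scene(tiny_gen(), seed = s)
    expect_equal(flood_fill_count(sc$truth_mask), sc$true_count)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(height = 128, width = 128,
                                radius_range = c(10, 80)),
               "exceeds the dish radius")
  expect_error(generator_config(reflection_prob = 2), "reflection_prob")
  expect_error(generate_scene(tiny_gen(), seed = "a"), "integer")
})

test_that("annotations round-trip through JSON", {
  sc <- generate_scene(tiny_gen(count_range = 5L, reflection_prob = 0),
                       seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_annotations(sc, path)
  back <- read_annotations(path)
  expect_equal(back$count, sc$true_count)
  expect_equal(nrow(back$colonies), 5)
  expect_equal(back$colonies$row, sc$colonies$row, tolerance = 1e-12)

  sc0 <- generate_scene(tiny_gen(count_range = 0L), seed = 3)
  write_annotations(sc0, path)
  expect_equal(nrow(read_annotations(path)$colonies), 0)

  sc_r <- generate_scene(tiny_gen(reflection_prob = 1), seed = 1)
  write_annotations(sc_r, path)
  expect_equal(read_annotations(path)$count, sc_r$true_count)
})

test_that("scene images and masks survive PNG round trips", {
  sc <- generate_scene(tiny_gen(h = 64, w = 64, count_range = 3L), seed = 4)
  img_path <- withr::local_tempfile(fileext = ".png")
  mask_path <- withr::local_tempfile(fileext = ".png")
  write_image_png(sc$image, img_path)
  write_image_png(sc$truth_mask, mask_path)
  img2 <- read_image_png(img_path)
  expect_equal(dim(img2), c(64, 64, 3))
  expect_lt(max(abs(img2 - sc$image)), 1 / 255)
  expect_identical(read_mask_png(mask_path), sc$truth_mask)
})
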