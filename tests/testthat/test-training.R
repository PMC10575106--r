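# training protocol: normalization, splits, checkpoint bookkeeping

test_that("z-score normalization standardizes channels without leakage", {
  set.seed(4)
  imgs <- lapply(1:6, function(i)
    array(runif(32 * 32 * 3, 0, i / 3), dim = c(32, 32, 3)))
  zn <- zscore_normalize(imgs)
  for (ch in 1:3) {
    v <- unlist(lapply(zn$images, function(im) as.vector(im[, , ch])))
    expect_lt(abs(mean(v)), 1e-6)
    expect_lt(abs(sd(v) - 1), 1e-6)
  }
  # stored statistics applied to new data: not an identity re-application
  other <- list(array(runif(32 * 32 * 3), dim = c(32, 32, 3)))
  zn2 <- zscore_normalize(other, zn$stats)
  expect_false(isTRUE(all.equal(zn2$images[[1]], other[[1]])))

  const <- list(array(runif(32 * 32 * 3), dim = c(32, 32, 3)))
  const[[1]][, , 2] <- 0.3
  expect_error(zscore_normalize(const), "channel 2")
})

test_that("k-fold splits are disjoint, exhaustive and deterministic", {
  f <- make_splits(150, list(type = "kfold", k = 5), seed = 3)
  expect_equal(as.vector(table(f)), rep(30, 5))
  expect_equal(sort(unique(f)), 1:5)
  expect_identical(make_splits(150, list(type = "kfold", k = 5), seed = 3),
                   f)
  expect_false(identical(
    make_splits(150, list(type = "kfold", k = 5), seed = 4), f))
  expect_error(make_splits(3, list(type = "kfold", k = 5)), "fewer")
})

test_that("random splits respect the 72/18/10 fractions", {
  s <- make_splits(50, seed = 8)
  expect_equal(sum(s == "train"), 36)
  expect_equal(sum(s == "val"), 9)
  expect_equal(sum(s == "test"), 5)
  expect_identical(make_splits(50, seed = 8), s)
  expect_error(make_splits(5), "at least")
  expect_error(
    make_splits(50, list(type = "random",
                         fractions = c(train = 0.5, val = 0.2,
                                       test = 0.2))),
    "sum to 1")
})

test_that("training records history, selects the argmin-MAE checkpoint,
           and keeps the alignment term bounded", {
  set.seed(12)
  gcfg <- generator_config(height = 64, width = 64, count_range = c(2, 6))
  scenes <- lapply(1:12, function(s) generate_scene(gcfg, seed = s))
  ucfg <- unet_config(levels = 3, base_channels = 4, input_size = 64)
  ds <- make_training_set(scenes, ucfg)
  mod <- build_model(ucfg, seed = 5)
  res <- train_unet(mod, ds, train_config(epochs = 3, batch_size = 4,
                                          seed = 21))
  expect_equal(nrow(res$history), 3)
  expect_equal(res$val_mae, min(res$history$val_mae))
  expect_equal(res$best_epoch,
               which(res$history$val_mae == res$val_mae)[1])
  expect_true(all(res$history$mid >= -1 & res$history$mid <= 0))
  expect_true(is.finite(res$val_mae_untrained))

  # normalization statistics come from the training split only
  tr_idx <- which(res$split == "train")
  zn <- zscore_normalize(lapply(ds[tr_idx], `[[`, "image"))
  expect_equal(res$model$norm_stats, zn$stats, tolerance = 1e-12)

  # learning-rate schedule follows the time-based decay
  cfgd <- train_config(epochs = 3)
  expect_equal(res$history$lr,
               cfgd$lr / (1 + cfgd$decay * (0:2)), tolerance = 1e-12)
})

test_that("training datasets resize scenes and follow the target style", {
  gcfg <- generator_config(height = 128, width = 128,
                           count_range = c(3, 5))
  sc <- generate_scene(gcfg, seed = 2)
  ucfg <- unet_config(levels = 3, base_channels = 4, input_size = 64)
  ds <- make_training_set(list(sc), ucfg)
  expect_equal(dim(ds[[1]]$image), c(64, 64, 3))
  expect_equal(dim(ds[[1]]$yout), c(64, 64))
  expect_equal(dim(ds[[1]]$ymid), c(16, 16))
  # annotated style counts every rendered blob, reflections included
  expect_equal(ds[[1]]$count, sc$true_count + nrow(sc$reflections))
  expect_lte(sum(ds[[1]]$ymid), ds[[1]]$count)

  ds_c <- make_training_set(list(sc), ucfg, targets = "colony_only")
  expect_equal(ds_c[[1]]$count, sc$true_count)
  expect_true(all(ds_c[[1]]$yout <= ds[[1]]$yout))
})
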