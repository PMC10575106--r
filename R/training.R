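# Training protocol: channel-wise z-score normalization with training-set
# statistics, deterministic splits, Adam with time-based learning-rate
# decay, and checkpoint selection by validation count MAE.

#' Channel-wise z-score normalization
#'
#' Standardizes each RGB channel as `(X - mu) / sigma`. When `stats` is
#' `NULL` the statistics are computed from the supplied images (the
#' training set); pass the returned `stats` to normalize validation and
#' test images without leakage.
#'
#' @param images a list of H x W x C arrays, or a single array.
#' @param stats optional list with `mean` and `sd` vectors (one entry per
#'   channel).
#' @return List with `images` (same structure, normalized) and `stats`.
#' @export
zscore_normalize <- function(images, stats = NULL) {
  single <- !is.list(images)
  if (single) images <- list(images)
  nc <- dim(images[[1]])[3]
  if (is.null(stats)) {
    mu <- sdv <- numeric(nc)
    for (ch in seq_len(nc)) {
      v <- unlist(lapply(images, function(im) as.vector(im[, , ch])))
      mu[ch] <- mean(v); sdv[ch] <- stats::sd(v)
      if (!is.finite(sdv[ch]) || sdv[ch] == 0)
        stop(sprintf("channel %d has zero variance; cannot z-score", ch))
    }
    stats <- list(mean = mu, sd = sdv)
  }
  out <- lapply(images, function(im) {
    for (ch in seq_len(nc))
      im[, , ch] <- (im[, , ch] - stats$mean[ch]) / stats$sd[ch]
    im
  })
  if (single) out <- out[[1]]
  list(images = out, stats = stats)
}

#' Deterministic train/validation/test splits
#'
#' Either k-fold cross-validation (disjoint, exhaustive folds) or a random
#' split with fixed fractions (defaults 72% train / 18% validation / 10%
#' test).
#'
#' @param n_items number of items to split.
#' @param split `list(type = "kfold", k = 5)` or `list(type = "random",
#'   fractions = c(train = 0.72, val = 0.18, test = 0.10))`.
#' @param seed integer seed; identical `(n_items, split, seed)` yield
#'   identical assignments.
#' @return For k-fold: integer vector of fold ids (1..k). For random: a
#'   character vector with values `"train"`, `"val"`, `"test"`.
#' @export
make_splits <- function(n_items,
                        split = list(type = "random",
                                     fractions = c(train = 0.72, val = 0.18,
                                                   test = 0.10)),
                        seed = 1L) {
  type <- split$type %||% "random"
  with_local_seed(seed, {
    if (type == "kfold") {
      k <- split$k %||% 5L
      if (k < 2L) stop("k-fold split needs k >= 2")
      if (n_items < k) stop("fewer items than folds")
      folds <- rep(seq_len(k), length.out = n_items)
      sample(folds)
    } else if (type == "random") {
      fr <- split$fractions %||% c(train = 0.72, val = 0.18, test = 0.10)
      if (abs(sum(fr) - 1) > 1e-8) stop("split fractions must sum to 1")
      if (n_items < 10L) stop("random split needs at least 10 items")
      n_test <- round(fr[["test"]] * n_items)
      n_val <- round(fr[["val"]] * n_items)
      lab <- rep("train", n_items)
      ord <- sample(n_items)
      lab[ord[seq_len(n_test)]] <- "test"
      lab[ord[n_test + seq_len(n_val)]] <- "val"
      lab
    } else stop("unknown split type: ", type)
  })
}

#' Training configuration
#'
#' @param epochs number of epochs.
#' @param lr initial Adam learning rate.
#' @param decay time-based decay coefficient `d` in
#'   `lr_t = lr / (1 + d * t)` with `t` the 0-based epoch; default
#'   `1 / epochs`.
#' @param batch_size gradient-accumulation batch size.
#' @param seed seed controlling the split and example order.
#' @param split passed to [make_splits()].
#' @param loss a [loss_config()]; the default is the multi-loss objective
#'   (Tversky + cross-entropy + bottleneck alignment) with per-pixel mean
#'   cross-entropy so all terms are on a comparable scale.
#' @return List of class `"train_config"`.
#' @export
train_config <- function(epochs = 10L, lr = 0.001, decay = NULL,
                         batch_size = 4L, seed = 42L,
                         split = list(type = "random",
                                      fractions = c(train = 0.72,
                                                    val = 0.18,
                                                    test = 0.10)),
                         loss = loss_config(combination = "tversky_ce_mid",
                                            ce_reduction = "mean")) {
  structure(list(epochs = as.integer(epochs), lr = lr,
                 decay = decay %||% (1 / epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), split = split, loss = loss),
            class = "train_config")
}

#' Turn generated scenes into a training dataset
#'
#' Builds, per scene, the raw image, the full-resolution segmentation
#' target, the coarse centroid indicator at the model's bottleneck
#' resolution, and the true count. With `targets = "annotated"` (the
#' default) the segmentation target is the visible mask and the indicator
#' covers every rendered blob, emulating real annotation pipelines in
#' which bezel reflections are indistinguishable from colonies and end up
#' labeled; the resulting segmenter reproduces the reflection
#' double-counting that the hybrid rule corrects. `targets =
#' "colony_only"` uses the generator's privileged knowledge to exclude
#' reflections from both maps.
#'
#' @param scenes list of [generate_scene()] results.
#' @param config a [unet_config()] (supplies input size and bottleneck
#'   grid).
#' @param targets `"annotated"` or `"colony_only"`.
#' @return List of items with `image`, `yout`, `ymid`, `count`.
#' @export
make_training_set <- function(scenes, config = unet_config(),
                              targets = c("annotated", "colony_only")) {
  targets <- match.arg(targets)
  lapply(scenes, function(sc) {
    img <- sc$image
    if (targets == "annotated") {
      yout <- sc$visible_mask
      colonies <- rbind(sc$colonies, sc$reflections)
      colonies$is_reflection <- FALSE   # annotations cannot tell them apart
    } else {
      yout <- sc$truth_mask
      colonies <- sc$colonies
    }
    # the per-item count is the annotated count (validation MAE compares
    # predictions against the same annotation source as the targets); the
    # expert colony count lives in the scene's true_count for test-time use
    item_count <- nrow(colonies)
    h0 <- dim(img)[1]
    if (h0 != config$input_size) {
      sc_fac <- config$input_size / h0
      img <- resize_bilinear(img, config$input_size, config$input_size)
      yout <- matrix(as.integer(
        resize_bilinear(yout + 0, config$input_size,
                        config$input_size) > 0.5),
        config$input_size, config$input_size)
      colonies$row <- (colonies$row - 0.5) * sc_fac + 0.5
      colonies$col <- (colonies$col - 0.5) * sc_fac + 0.5
    }
    list(image = img, yout = yout,
         ymid = build_ymid(colonies, config$input_size, config$input_size,
                           config$m),
         count = item_count)
  })
}

# gradient of the Tversky loss with respect to the probability map
tversky_grad <- function(p, y, alpha, beta, smooth = 1e-5) {
  dP <- matrix(0, nrow(p), ncol(p))
  nc <- ncol(p)
  for (ch in seq_len(nc)) {
    x <- p[, ch]; t <- y[, ch]
    tp <- sum(x * t); fn <- sum((1 - x) * t); fp <- sum(x * (1 - t))
    den <- tp + alpha * fn + beta * fp + smooth
    num <- tp + smooth
    # d(1 - num/den)/dx_i = -(t_i * den - num * dden_i) / den^2
    dden <- (1 - alpha) * t + beta * (1 - t)
    dP[, ch] <- -(t * den - num * dden) / den^2 / nc
  }
  dP
}

# assemble total loss and the gradient at the logits / bottleneck tap
loss_and_grads <- function(fwd, yout_hot, ymid, cfg) {
  n <- nrow(fwd$cache$p)
  p <- fwd$cache$p
  yh <- matrix(yout_hot, n, 2L)
  comb <- loss_combined(fwd$xmid, fwd$xout, ymid,
                        array(yh, dim = c(fwd$h, fwd$w, 2L)), cfg)
  use_mid <- cfg$combination %in% c("tversky_ce_mid", "eq_sum")
  # cross-entropy (+ softmax) gradient
  dlog <- (p - yh)
  if (cfg$ce_reduction == "mean") dlog <- dlog / n
  if (cfg$combination %in% c("tversky_ce", "tversky_ce_mid")) {
    dP <- tversky_grad(p, yh, cfg$tversky_alpha, cfg$tversky_beta)
    dlog <- dlog + p * (dP - rowSums(dP * p))
  } else {
    # dice gradient (standard variant) when training with the summed form
    dP <- dice_grad(p, yh, cfg)
    dlog <- dlog + p * (dP - rowSums(dP * p))
  }
  dxmid <- NULL
  if (use_mid) {
    x <- fwd$xmid; yv <- ymid
    fx <- sqrt(sum(x^2)); fy <- sqrt(sum(yv^2))
    if (fx > 0 && fy > 0)
      dxmid <- -yv / (fx * fy) + sum(x * yv) * x / (fx^3 * fy)
  }
  list(loss = comb, dlogits = dlog, dxmid = dxmid)
}

dice_grad <- function(p, yh, cfg) {
  dP <- matrix(0, nrow(p), ncol(p))
  eps <- cfg$epsilon
  for (ch in 1:2) {
    x <- p[, ch]; t <- yh[, ch]
    if (cfg$dice_variant == "as_printed") {
      sx <- sum(x); st <- sum(t); inter <- sum(x * t)
      den <- sx * st + eps
      dP[, ch] <- -(t * den - inter * st) / den^2
    } else {
      sx <- sum(x); st <- sum(t); inter <- sum(x * t)
      den <- sx + st + eps
      dP[, ch] <- -(2 * t * den - 2 * inter) / den^2
    }
  }
  dP
}

# recursive Adam update over the nested weight lists
adam_step <- function(w, g, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  t <- st$t
  upd <- function(wi, gi, mi, vi) {
    mi <- b1 * mi + (1 - b1) * gi
    vi <- b2 * vi + (1 - b2) * gi^2
    mhat <- mi / (1 - b1^t); vhat <- vi / (1 - b2^t)
    list(w = wi - lr * mhat / (sqrt(vhat) + eps), m = mi, v = vi)
  }
  walk <- function(wi, gi, mi, vi) {
    if (is.list(wi)) {
      out_w <- wi; out_m <- mi; out_v <- vi
      for (nm in seq_along(wi)) {
        r <- walk(wi[[nm]], gi[[nm]], mi[[nm]], vi[[nm]])
        out_w[[nm]] <- r$w; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(w = out_w, m = out_m, v = out_v)
    } else upd(wi, gi, mi, vi)
  }
  r <- walk(w, g, st$m, st$v)
  list(w = r$w, st = list(m = r$m, v = r$v, t = t))
}

zeros_like <- function(w) rapply(w, function(x) x * 0, how = "replace")

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) {
    for (nm in seq_along(a)) a[[nm]] <- add_grads(a[[nm]], b[[nm]])
    a
  } else a + b
}

# naive count MAE of thresholded predictions on a set of items
validation_mae <- function(model, items, stats) {
  preds <- vapply(items, function(it) {
    pr <- predict_segmentation(model, it$image, stats)
    count_regions(pr$mask)$n_regions
  }, numeric(1))
  truth <- vapply(items, `[[`, numeric(1), "count")
  mean(abs(truth - preds))
}

#' Train a segmentation model with validation-MAE checkpointing
#'
#' Adam optimization of the configured loss with a time-based
#' learning-rate decay (`lr_t = lr / (1 + d * t)`). After each epoch the
#' mean absolute error of naive region counts on the validation set is
#' computed from thresholded predictions; the weights with the lowest
#' validation MAE are retained (ties resolved toward the earlier epoch).
#' Channel statistics are computed on the training split only.
#'
#' @param model a [build_model()] object.
#' @param dataset output of [make_training_set()].
#' @param config a [train_config()].
#' @return List with `model` (best checkpoint, `norm_stats` attached),
#'   `history` (one row per epoch: loss terms and validation MAE),
#'   `best_epoch`, `val_mae` (best), and `val_mae_untrained` (validation
#'   MAE of the initialized model before any update).
#' @export
train_unet <- function(model, dataset, config = train_config()) {
  n <- length(dataset)
  assign_split <- make_splits(n, config$split, config$seed)
  if (identical(config$split$type, "kfold")) {
    tr_idx <- which(assign_split != 1L)
    va_idx <- which(assign_split == 1L)
  } else {
    tr_idx <- which(assign_split == "train")
    va_idx <- which(assign_split == "val")
  }
  train_items <- dataset[tr_idx]; val_items <- dataset[va_idx]
  zn <- zscore_normalize(lapply(train_items, `[[`, "image"))
  stats <- zn$stats
  ximgs <- zn$images

  lcfg <- config$loss
  wts <- model$weights
  adam <- list(m = zeros_like(wts), v = zeros_like(wts), t = 0)
  mae0 <- validation_mae(model, val_items, stats)
  best <- list(mae = Inf, weights = wts, epoch = 0L)
  term_names <- names(loss_combined(
    matrix(1, 2, 2), array(0.5, c(4, 4, 2)), matrix(1, 2, 2),
    one_hot(matrix(0L, 4, 4)), lcfg)$terms)
  hist_rows <- vector("list", config$epochs)

  with_local_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      lr_t <- config$lr / (1 + config$decay * (epoch - 1))
      ord <- sample(length(train_items))
      acc <- NULL; acc_n <- 0L
      term_sums <- numeric(length(term_names)); n_seen <- 0L
      for (i in ord) {
        it <- train_items[[i]]
        fwd <- unet_forward(list2env_model(model, wts), ximgs[[i]],
                            cache = TRUE)
        lg <- loss_and_grads(fwd, one_hot(it$yout), it$ymid, lcfg)
        if (!is.finite(lg$loss$total))
          stop(sprintf(
            "non-finite loss at epoch %d (item %d): %s", epoch, i,
            paste(sprintf("%s=%.4g", names(lg$loss$terms), lg$loss$terms),
                  collapse = ", ")))
        term_sums <- term_sums + lg$loss$terms; n_seen <- n_seen + 1L
        g <- unet_backward(list2env_model(model, wts), fwd,
                           lg$dlogits, lg$dxmid)
        g <- g[names(wts)]
        acc <- add_grads(acc, g); acc_n <- acc_n + 1L
        if (acc_n >= config$batch_size) {
          adam$t <- adam$t + 1
          stp <- adam_step(wts, acc, adam, lr_t)
          wts <- stp$w; adam <- stp$st
          acc <- NULL; acc_n <- 0L
        }
      }
      if (acc_n > 0L) {
        adam$t <- adam$t + 1
        stp <- adam_step(wts, acc, adam, lr_t)
        wts <- stp$w; adam <- stp$st
      }
      cur_model <- list2env_model(model, wts)
      vmae <- validation_mae(cur_model, val_items, stats)
      if (vmae < best$mae) best <- list(mae = vmae, weights = wts,
                                        epoch = epoch)
      hist_rows[[epoch]] <- c(epoch = epoch, lr = lr_t,
                              term_sums / max(n_seen, 1L), val_mae = vmae)
    }
  })
  history <- as.data.frame(do.call(rbind, hist_rows))
  final <- model
  final$weights <- best$weights
  final$norm_stats <- stats
  list(model = final, history = history, best_epoch = best$epoch,
       val_mae = best$mae, val_mae_untrained = mae0,
       split = assign_split)
}

# cheap "with these weights" view of a model
list2env_model <- function(model, wts) {
  model$weights <- wts
  model
}
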