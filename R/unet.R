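# Compact U-Net family implemented directly on BLAS matrix products.
# Feature maps live as (H*W) x C matrices (column-major spatial flatten);
# 3x3 convolutions are nine shifted gemms, downsampling is a strided 3x3
# convolution, decoder stages fuse skip and upsampled features with 1x1
# convolutions. The bottleneck tap averages feature channels into a single
# m x m map consumed by the alignment loss.

#' U-Net configuration
#'
#' @param levels number of resolution levels (default 5: four halvings, so
#'   a 1024-px input yields a 64 x 64 bottleneck grid and a 256-px input a
#'   16 x 16 grid).
#' @param base_channels channels at the finest level (8 suits small
#'   fixtures; 32 a full-scale model).
#' @param input_size input image side in pixels; must be divisible by
#'   `2^(levels - 1)`.
#' @param variant `"plain"` or `"residual"` (adds identity skips around
#'   equal-width encoder convolutions).
#' @param channel_cap channel growth is capped at `channel_cap *
#'   base_channels` to bound the bottleneck width.
#' @return List of class `"unet_config"` with derived field `m`, the
#'   bottleneck grid size.
#' @export
unet_config <- function(levels = 5L, base_channels = 8L, input_size = 256L,
                        variant = c("plain", "residual"),
                        channel_cap = 4L) {
  variant <- match.arg(variant)
  stride_total <- 2^(levels - 1L)
  if (input_size %% stride_total != 0L)
    stop("`input_size` must be divisible by 2^(levels - 1)")
  structure(list(levels = as.integer(levels),
                 base_channels = as.integer(base_channels),
                 input_size = as.integer(input_size), variant = variant,
                 channel_cap = as.integer(channel_cap),
                 classes = 2L,
                 m = as.integer(input_size / stride_total)),
            class = "unet_config")
}

unet_channels <- function(config) {
  pmin(config$base_channels * 2^(seq_len(config$levels) - 1L),
       config$channel_cap * config$base_channels)
}

# --- index maps for shifted gemms (memoized per geometry) ----------------

.idx_cache <- new.env(parent = emptyenv())

# source index (into an (H*W + 1)-row matrix whose last row is zeros) for
# each of the nine 3x3 offsets; stride 1 or 2
conv_idx <- function(h, w, stride = 1L) {
  key <- paste(h, w, stride, sep = "_")
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  ho <- h %/% stride; wo <- w %/% stride
  rout <- rep(seq_len(ho), times = wo) * stride - (stride - 1L)
  cout <- rep(seq_len(wo), each = ho) * stride - (stride - 1L)
  zero_row <- h * w + 1L
  idx <- vector("list", 9L)
  k <- 0L
  for (dc in -1L:1L) for (dr in -1L:1L) {
    k <- k + 1L
    rs <- rout + dr; cs <- cout + dc
    ii <- rs + (cs - 1L) * h
    ii[rs < 1L | rs > h | cs < 1L | cs > w] <- zero_row
    idx[[k]] <- ii
  }
  .idx_cache[[key]] <- idx
  idx
}

upsample_idx <- function(h2, w2) {           # fine grid -> parent index
  key <- paste("up", h2, w2, sep = "_")
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  hf <- 2L * h2
  rf <- rep(seq_len(hf), times = 2L * w2)
  cf <- rep(seq_len(2L * w2), each = hf)
  idx <- (ceiling(rf / 2) + (ceiling(cf / 2) - 1L) * h2)
  .idx_cache[[key]] <- idx
  idx
}

# --- layer primitives ----------------------------------------------------

conv3_fwd <- function(x, layer, idx) {
  xa <- rbind(x, 0)
  y <- matrix(0, length(idx[[1]]), ncol(layer$W[[1]]))
  for (k in 1:9) y <- y + xa[idx[[k]], , drop = FALSE] %*% layer$W[[k]]
  sweep(y, 2L, layer$b, `+`)
}

conv3_bwd <- function(x, dy, layer, idx) {
  xa <- rbind(x, 0)
  n <- nrow(x)
  dxa <- matrix(0, n + 1L, ncol(x))
  dW <- vector("list", 9L)
  for (k in 1:9) {
    xs <- xa[idx[[k]], , drop = FALSE]
    dW[[k]] <- crossprod(xs, dy)
    dxa[idx[[k]], ] <- dxa[idx[[k]], , drop = FALSE] + dy %*% t(layer$W[[k]])
  }
  list(dx = dxa[seq_len(n), , drop = FALSE],
       grad = list(W = dW, b = colSums(dy)))
}

conv1_fwd <- function(x, layer) sweep(x %*% layer$W, 2L, layer$b, `+`)

conv1_bwd <- function(x, dy, layer) {
  list(dx = dy %*% t(layer$W),
       grad = list(W = crossprod(x, dy), b = colSums(dy)))
}

relu <- function(x) { x[x < 0] <- 0; x }

softmax2 <- function(z) {
  zm <- pmax(z[, 1], z[, 2])
  e1 <- exp(z[, 1] - zm); e2 <- exp(z[, 2] - zm)
  s <- e1 + e2
  cbind(e1 / s, e2 / s)
}

init_conv3 <- function(cin, cout) {
  sd <- sqrt(2 / (9 * cin))
  list(W = lapply(1:9, function(k) matrix(rnorm(cin * cout, 0, sd),
                                          cin, cout)),
       b = numeric(cout))
}

init_conv1 <- function(cin, cout) {
  sd <- sqrt(2 / cin)
  list(W = matrix(rnorm(cin * cout, 0, sd), cin, cout), b = numeric(cout))
}

#' Build an untrained segmentation model
#'
#' Encoder: one 3x3 convolution + ReLU per level, with strided 3x3
#' convolutions between levels; the `"residual"` variant adds identity
#' skips around equal-width encoder convolutions. Decoder: nearest-neighbor
#' upsampling fused with the encoder skip through a 3x3 convolution + ReLU.
#' A 1x1 head with softmax yields two-class per-pixel probabilities. The
#' bottleneck feature map is channel-averaged into a single nonnegative
#' m x m map (`xmid`).
#'
#' @param config a [unet_config()].
#' @param seed integer seed for weight initialization (He-scaled normal).
#' @return Object of class `"cfu_unet"`: list with `config`, `weights`,
#'   and `norm_stats` (filled in by training).
#' @export
build_model <- function(config = unet_config(), seed = 1L) {
  L <- config$levels
  ch <- unet_channels(config)
  with_local_seed(seed, {
    wts <- list()
    for (l in seq_len(L)) {
      cin <- if (l == 1L) 3L else ch[l]
      wts[[paste0("enc", l)]] <- init_conv3(cin, ch[l])
      if (l < L)
        wts[[paste0("down", l)]] <- init_conv3(ch[l], ch[l + 1L])
    }
    for (l in seq_len(L - 1L))
      wts[[paste0("dec", l)]] <- init_conv3(ch[l] + ch[l + 1L], ch[l])
    wts[["head"]] <- init_conv1(ch[1L], 2L)
    # class-prior bias: start predictions at the sparse foreground prior
    # so the cross-entropy term opens near its floor and the overlap loss
    # drives learning from the first step (avoids the all-background
    # plateau on short training budgets)
    wts[["head"]]$b <- c(log(0.98), log(0.02))
    structure(list(config = config, weights = wts, norm_stats = NULL),
              class = "cfu_unet")
  })
}

#' @export
print.cfu_unet <- function(x, ...) {
  np <- sum(rapply(x$weights, length, how = "unlist"))
  cat(sprintf(
    "cfu_unet (%s): %d levels, base %d ch, input %d px, bottleneck %dx%d, %d parameters\n",
    x$config$variant, x$config$levels, x$config$base_channels,
    x$config$input_size, x$config$m, x$config$m, np))
  invisible(x)
}

# full forward pass; cache = TRUE retains intermediates for backprop
unet_forward <- function(model, ximg, cache = FALSE) {
  cfg <- model$config; L <- cfg$levels
  h <- dim(ximg)[1]; w <- dim(ximg)[2]
  if (h %% 2^(L - 1L) != 0L || w %% 2^(L - 1L) != 0L)
    stop("input size incompatible with the number of levels")
  if (anyNA(ximg)) stop("input contains NA/NaN; normalize the image first")
  wts <- model$weights
  residual <- cfg$variant == "residual"
  x <- matrix(ximg, h * w, 3L)
  hs <- h %/% 2^(seq_len(L) - 1L); ws <- w %/% 2^(seq_len(L) - 1L)
  a <- dpre <- vector("list", L)       # a: post-ReLU encoder features
  enc_in <- vector("list", L)
  cur <- x
  for (l in seq_len(L)) {
    enc_in[[l]] <- cur
    idx <- conv_idx(hs[l], ws[l], 1L)
    z <- conv3_fwd(cur, wts[[paste0("enc", l)]], idx)
    if (residual && l > 1L) z <- z + cur
    a[[l]] <- relu(z)
    if (l < L) {
      idxd <- conv_idx(hs[l], ws[l], 2L)
      cur <- relu(conv3_fwd(a[[l]], wts[[paste0("down", l)]], idxd))
    }
  }
  mfeat <- rowMeans(a[[L]])
  xmid <- matrix(abs(mfeat), hs[L], ws[L])
  b <- cats <- vector("list", L)
  prev <- a[[L]]
  for (l in (L - 1L):1L) {
    up <- prev[upsample_idx(hs[l + 1L], ws[l + 1L]), , drop = FALSE]
    cats[[l]] <- cbind(a[[l]], up)
    b[[l]] <- relu(conv3_fwd(cats[[l]], wts[[paste0("dec", l)]],
                             conv_idx(hs[l], ws[l], 1L)))
    prev <- b[[l]]
  }
  logits <- conv1_fwd(b[[1L]], wts[["head"]])
  p <- softmax2(logits)
  res <- list(
    xout = array(p, dim = c(h, w, 2L)),
    xmid = xmid, h = h, w = w)
  if (cache)
    res$cache <- list(a = a, b = b, cats = cats, enc_in = enc_in,
                      p = p, mfeat = mfeat, hs = hs, ws = ws)
  res
}

# backward pass: dlogits (n x 2) from the output losses, dxmid (m x m)
# from the alignment loss; returns gradients in the weights layout
unet_backward <- function(model, fwd, dlogits, dxmid = NULL) {
  cfg <- model$config; L <- cfg$levels
  wts <- model$weights
  residual <- cfg$variant == "residual"
  cc <- fwd$cache
  hs <- cc$hs; ws <- cc$ws
  grads <- list()

  hb <- conv1_bwd(cc$b[[1L]], dlogits, wts[["head"]])
  grads[["head"]] <- hb$grad
  dskip <- vector("list", L)          # gradient arriving at each a[[l]]
  dprev <- hb$dx
  for (l in seq_len(L - 1L)) {
    dprev[cc$b[[l]] <= 0] <- 0
    db <- conv3_bwd(cc$cats[[l]], dprev, wts[[paste0("dec", l)]],
                    conv_idx(hs[l], ws[l], 1L))
    grads[[paste0("dec", l)]] <- db$grad
    nskip <- ncol(cc$a[[l]])
    dskip[[l]] <- db$dx[, seq_len(nskip), drop = FALSE]
    dup <- db$dx[, -seq_len(nskip), drop = FALSE]
    # nearest-neighbor upsample backward: sum the four children
    idx <- upsample_idx(hs[l + 1L], ws[l + 1L])
    dprev <- rowsum(dup, idx, reorder = TRUE)
  }
  da <- dprev                          # arrives at the bottleneck a[[L]]
  if (!is.null(dxmid)) {
    sgn <- ifelse(cc$mfeat > 0, 1, ifelse(cc$mfeat < 0, -1, 0))
    da <- da + (as.vector(dxmid) * sgn / ncol(cc$a[[L]]))
  }
  for (l in L:1L) {
    if (l < L) da <- da + dskip[[l]]
    da[cc$a[[l]] <= 0] <- 0
    idx <- conv_idx(hs[l], ws[l], 1L)
    eb <- conv3_bwd(cc$enc_in[[l]], da, wts[[paste0("enc", l)]], idx)
    grads[[paste0("enc", l)]] <- eb$grad
    dx <- eb$dx
    if (residual && l > 1L) dx <- dx + da
    if (l > 1L) {
      # through the strided down-convolution into a[[l-1]]
      down <- wts[[paste0("down", l - 1L)]]
      dcur <- dx
      dcur[cc$enc_in[[l]] <= 0] <- 0
      idxd <- conv_idx(hs[l - 1L], ws[l - 1L], 2L)
      n_in <- hs[l - 1L] * ws[l - 1L]
      dxa <- matrix(0, n_in + 1L, ncol(cc$a[[l - 1L]]))
      xa <- rbind(cc$a[[l - 1L]], 0)
      dWd <- vector("list", 9L)
      for (k in 1:9) {
        xs <- xa[idxd[[k]], , drop = FALSE]
        dWd[[k]] <- crossprod(xs, dcur)
        dxa[idxd[[k]], ] <- dxa[idxd[[k]], , drop = FALSE] +
          dcur %*% t(down$W[[k]])
      }
      grads[[paste0("down", l - 1L)]] <-
        list(W = dWd, b = colSums(dcur))
      da <- dxa[seq_len(n_in), , drop = FALSE]
    }
  }
  grads
}

#' Run inference and threshold to a binary mask
#'
#' Normalizes the image with the model's stored channel statistics (or the
#' supplied ones), resizes bilinearly to the configured input size if
#' needed, and thresholds the two-class probability map by argmax.
#'
#' @param model a trained [build_model()] object.
#' @param image H x W x 3 array in \[0, 1\] (raw, unnormalized).
#' @param norm_stats optional list with `mean` and `sd` per channel;
#'   defaults to `model$norm_stats`.
#' @return List with `mask` (binary matrix at input resolution), `xout`
#'   (probability array), `xmid` (bottleneck map).
#' @export
predict_segmentation <- function(model, image, norm_stats = NULL) {
  stats <- norm_stats %||% model$norm_stats
  if (is.null(stats))
    stop("no normalization statistics: train the model or pass `norm_stats`")
  sz <- model$config$input_size
  if (dim(image)[1] != sz || dim(image)[2] != sz)
    image <- resize_bilinear(image, sz, sz)
  for (ch in 1:3)
    image[, , ch] <- (image[, , ch] - stats$mean[ch]) / stats$sd[ch]
  fwd <- unet_forward(model, image)
  mask <- matrix(as.integer(fwd$xout[, , 2] > fwd$xout[, , 1]),
                 dim(image)[1], dim(image)[2])
  list(mask = mask, xout = fwd$xout, xmid = fwd$xmid)
}

#' Bilinear image resize
#'
#' @param image H x W matrix or H x W x C array.
#' @param h,w target size.
#' @return Resized image.
#' @export
resize_bilinear <- function(image, h, w) {
  one <- function(m) {
    hi <- nrow(m); wi <- ncol(m)
    ry <- (seq_len(h) - 0.5) * hi / h + 0.5
    rx <- (seq_len(w) - 0.5) * wi / w + 0.5
    y0 <- clamp(floor(ry), 1, hi); y1 <- clamp(y0 + 1, 1, hi)
    x0 <- clamp(floor(rx), 1, wi); x1 <- clamp(x0 + 1, 1, wi)
    fy <- clamp(ry - y0, 0, 1); fx <- clamp(rx - x0, 0, 1)
    top <- m[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx) +
      m[y0, x1, drop = FALSE] * outer(1 - fy, fx)
    bot <- m[y1, x0, drop = FALSE] * outer(fy, 1 - fx) +
      m[y1, x1, drop = FALSE] * outer(fy, fx)
    top + bot
  }
  if (is.matrix(image)) return(one(image))
  out <- array(0, dim = c(h, w, dim(image)[3]))
  for (ch in seq_len(dim(image)[3])) out[, , ch] <- one(image[, , ch])
  out
}
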