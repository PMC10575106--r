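# Independent oracles used throughout the suite. These deliberately use
# naive algorithms (stack-based flood fill, exhaustive accumulators,
# direct formula evaluation) so they share no code with the package paths
# they check.

# stack-based flood-fill connected-component count
flood_fill_count <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  if (connectivity == 8) {
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1)
    dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    dr <- c(-1, 1, 0, 0); dc <- c(0, 0, -1, 1)
  }
  count <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (mask[i, j] != 1 || seen[i, j]) next
    count <- count + 1L
    stack <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(stack) > 0L) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_along(dr)) {
        r2 <- p[1] + dr[k]; c2 <- p[2] + dc[k]
        if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w &&
            mask[r2, c2] == 1 && !seen[r2, c2]) {
          seen[r2, c2] <- TRUE
          stack[[length(stack) + 1L]] <- c(r2, c2)
        }
      }
    }
  }
  count
}

# exhaustive circle-Hough accumulator: counts edge pixels whose distance
# to each candidate bin center lies within half a spatial bin of each
# candidate radius; returns the argmax bin triple (by, bx, ir)
brute_force_hough_argmax <- function(edges, r_range, bin_xy = 2,
                                     bin_r = 2) {
  h <- nrow(edges); w <- ncol(edges)
  fg <- which(edges == 1)
  py <- (fg - 1) %% h + 1
  px <- (fg - 1) %/% h + 1
  nx <- ceiling(w / bin_xy); ny <- ceiling(h / bin_xy)
  r_bins <- seq(r_range[1], r_range[2], by = bin_r)
  best <- c(0, 0, 0); best_v <- -1
  for (ir in seq_along(r_bins)) for (bx in seq_len(nx)) {
    cx <- (bx - 0.5) * bin_xy
    dx2 <- (px - cx)^2
    for (by in seq_len(ny)) {
      cy <- (by - 0.5) * bin_xy
      d <- sqrt(dx2 + (py - cy)^2)
      v <- sum(abs(d - r_bins[ir]) <= 0.5 * bin_xy)
      if (v > best_v) { best_v <- v; best <- c(by, bx, ir) }
    }
  }
  list(bin = best, votes = best_v, r = r_bins[best[3]],
       x0 = (best[2] - 0.5) * bin_xy, y0 = (best[1] - 0.5) * bin_xy)
}

# rasterize a clean one-pixel-wide circle edge map
raster_circle_edges <- function(h, w, y0, x0, r, width = 0.6) {
  d <- sqrt(outer((seq_len(h) - y0)^2, (seq_len(w) - x0)^2, `+`))
  matrix(as.integer(abs(d - r) <= width), h, w)
}

# perfect dish localization built from a scene's ground-truth circles
truth_localization <- function(scene) {
  h <- dim(scene$image)[1]; w <- dim(scene$image)[2]
  d <- sqrt(outer((seq_len(h) - scene$dish$y0)^2,
                  (seq_len(w) - scene$dish$x0)^2, `+`))
  bezel <- matrix(0L, h, w)
  bezel[d > scene$water$r & d <= scene$dish$r] <- 1L
  structure(list(c1 = scene$dish, c2 = scene$glass, c3 = scene$water,
                 bezel_mask = bezel, found = TRUE),
            class = "dish_localization")
}

# a localization object representing failure
failed_localization <- function(h, w) {
  structure(list(c1 = NULL, c2 = NULL, c3 = NULL,
                 bezel_mask = matrix(0L, h, w), found = FALSE),
            class = "dish_localization")
}

# sparse blob mask sampler: a few discs plus salt noise
random_blob_mask <- function(h = 64, w = 64, n_discs = 4,
                             noise_frac = 0.02) {
  m <- matrix(0L, h, w)
  for (i in seq_len(n_discs)) {
    r0 <- runif(1, 6, h - 6); c0 <- runif(1, 6, w - 6)
    rad <- runif(1, 1.5, 4)
    d <- sqrt(outer((seq_len(h) - r0)^2, (seq_len(w) - c0)^2, `+`))
    m[d <= rad] <- 1L
  }
  m[sample(h * w, round(noise_frac * h * w))] <- 1L
  m
}

# direct smoothed-dice-loss evaluation (independent of loss_tversky)
smoothed_dice_loss <- function(x, y, smooth = 1e-5) {
  nc <- dim(x)[3]
  acc <- 0
  for (ch in seq_len(nc)) {
    tp <- sum(x[, , ch] * y[, , ch])
    acc <- acc + 1 -
      (2 * tp + 2 * smooth) /
        (sum(x[, , ch]) + sum(y[, , ch]) + 2 * smooth)
  }
  acc / nc
}

# small generator config used by fast unit tests
tiny_gen <- function(h = 256, w = 256, ...) {
  generator_config(height = h, width = w, ...)
}
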