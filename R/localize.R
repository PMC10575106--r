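# Petri dish localization: blur -> edge detection -> circle Hough ->
# C1 (dish edge) / C2 (glass edge) / C3 (water edge) cascade -> bezel mask.

#' Gaussian blur configuration
#' @param sigma kernel standard deviation in pixels.
#' @param truncate kernel support radius in multiples of `sigma`.
#' @return List of class `"blur_config"`.
#' @export
blur_config <- function(sigma = 2.0, truncate = 3.0) {
  if (!is_scalar_num(sigma) || sigma <= 0) stop("`sigma` must be > 0")
  structure(list(sigma = sigma, truncate = truncate), class = "blur_config")
}

#' Two-dimensional Gaussian kernel
#'
#' Evaluates the isotropic 2-D Gaussian density
#' `G(x, y) = exp(-(x^2 + y^2) / (2 sigma^2)) / (2 pi sigma^2)` on an
#' integer grid of half-width `ceiling(truncate * sigma)`. With
#' `normalize = TRUE` (the default used for filtering) the discretized
#' kernel is rescaled to unit sum so convolution conserves total intensity.
#'
#' @param sigma standard deviation in pixels.
#' @param truncate support radius in multiples of `sigma`.
#' @param normalize rescale to unit sum.
#' @return Square numeric matrix of odd size.
#' @export
gaussian_kernel <- function(sigma, truncate = 3.0, normalize = TRUE) {
  if (!is_scalar_num(sigma) || sigma <= 0) stop("`sigma` must be > 0")
  k <- ceiling(truncate * sigma)
  ax <- -k:k
  g <- exp(-outer(ax^2, ax^2, `+`) / (2 * sigma^2)) / (2 * pi * sigma^2)
  if (normalize) g <- g / sum(g)
  g
}

# reflective ("symmetric") padding of a matrix by k pixels on each side
pad_reflect <- function(m, k) {
  h <- nrow(m); w <- ncol(m)
  ri <- c(rev(seq_len(k)), seq_len(h), h + 1 - seq_len(k))
  ci <- c(rev(seq_len(k)), seq_len(w), w + 1 - seq_len(k))
  m[ri, ci]
}

filter2_reflect <- function(m, kern) {
  k <- (nrow(kern) - 1L) %/% 2L
  p <- pad_reflect(m, k)
  out <- EBImage::filter2(p, kern)
  out[(k + 1):(k + nrow(m)), (k + 1):(k + ncol(m))]
}

#' Gaussian blur with reflective boundary handling
#'
#' Convolution with the unit-sum discretized 2-D Gaussian kernel; applied
#' per channel for multi-channel input.
#'
#' @param image H x W matrix or H x W x C array.
#' @param config a [blur_config()].
#' @return Blurred image of the same shape.
#' @export
gaussian_blur <- function(image, config = blur_config()) {
  kern <- gaussian_kernel(config$sigma, config$truncate)
  if (is.matrix(image)) return(filter2_reflect(image, kern))
  out <- image
  for (ch in seq_len(dim(image)[3]))
    out[, , ch] <- filter2_reflect(image[, , ch], kern)
  out
}

# Canny edge detector returning the binary edge map plus Sobel gradients
canny_edges <- function(img, low = NULL, high = NULL,
                        percentiles = c(0.70, 0.90)) {
  if (!is.matrix(img)) stop("edge detection expects a single-channel image")
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)   # d/dcol
  sy <- t(sx)                                           # d/drow
  gx <- filter2_reflect(img, sx)
  gy <- filter2_reflect(img, sy)
  mag <- sqrt(gx^2 + gy^2)
  if (is.null(low) || is.null(high)) {
    pos <- mag[mag > 1e-12]
    if (length(pos) == 0L)
      return(list(edges = matrix(0L, nrow(img), ncol(img)), gx = gx, gy = gy))
    qs <- stats::quantile(pos, percentiles, names = FALSE)
    if (is.null(low)) low <- qs[1]
    if (is.null(high)) high <- qs[2]
  }
  if (low >= high) stop("`low` threshold must be below `high`")
  h <- nrow(img); w <- ncol(img)

  # non-maximum suppression along the quantized gradient direction
  ang <- atan2(gy, gx)
  sector <- (round(ang / (pi / 4)) %% 4)                # 0:E,1:NE,2:N,3:NW
  shift_mat <- function(m, dr, dc) {
    out <- matrix(0, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  dirs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))     # (drow, dcol)
  n1 <- n2 <- matrix(0, h, w)
  for (s in 0:3) {
    d <- dirs[[s + 1]]
    sel <- sector == s
    n1[sel] <- shift_mat(mag, -d[1], -d[2])[sel]
    n2[sel] <- shift_mat(mag,  d[1],  d[2])[sel]
  }
  nms <- mag
  nms[mag < n1 | mag < n2] <- 0

  strong <- nms >= high
  weak <- nms >= low
  if (!any(strong))
    return(list(edges = matrix(0L, h, w), gx = gx, gy = gy))
  lab <- label_components(matrix(as.integer(weak), h, w), 8)
  keep <- unique(lab$labels[strong])
  keep <- keep[keep > 0L]
  edges <- matrix(0L, h, w)
  edges[lab$labels %in% keep] <- 1L
  list(edges = edges, gx = gx, gy = gy)
}

#' Canny edge detection
#'
#' Sobel gradient magnitude, non-maximum suppression along the quantized
#' gradient direction, and hysteresis thresholding. Default thresholds are
#' the 70th and 90th percentiles of the positive gradient magnitudes.
#'
#' @param image single-channel H x W matrix (blur first for noisy input).
#' @param low,high hysteresis thresholds on gradient magnitude; `NULL`
#'   selects them from `percentiles`.
#' @param percentiles percentile pair used when thresholds are `NULL`.
#' @return Binary H x W edge matrix.
#' @export
detect_edges <- function(image, low = NULL, high = NULL,
                         percentiles = c(0.70, 0.90)) {
  if (!is.null(low) && !is.null(high) && low >= high)
    stop("`low` threshold must be below `high`")
  canny_edges(image, low, high, percentiles)$edges
}

#' Circle Hough transform with a 3-D accumulator
#'
#' Every edge pixel votes into an accumulator `A(x0, y0, r)`. With
#' `method = "cone"` (the textbook transform) a pixel votes for all centers
#' on its candidate cone, i.e. the full circle of radius `r` around it, for
#' every candidate radius. With `method = "gradient"` votes are cast only
#' along the local gradient direction (two antipodal candidates per radius),
#' which is orders of magnitude cheaper and well suited to strong circular
#' edges; it requires the Sobel gradients `gx`, `gy`.
#'
#' Peaks are local maxima of the accumulator, greedily extracted in order
#' of decreasing votes (ties broken by larger radius, then smaller row and
#' column) with non-maximum suppression of neighboring bins; each peak is
#' refined to sub-bin accuracy by the vote-weighted centroid of its 3x3x3
#' neighborhood.
#'
#' @param edges binary H x W edge matrix.
#' @param r_range radius search range in pixels, `c(r_min, r_max)`.
#' @param bin_xy,bin_r accumulator bin sizes in pixels.
#' @param top_k number of peaks to return.
#' @param method `"cone"` or `"gradient"`.
#' @param gx,gy Sobel gradients (required for `method = "gradient"`).
#' @param return_votes also return the raw accumulator (used by the
#'   localization cascade).
#' @return List of peaks, each a list with `circle` (a [circle()]) and
#'   `votes`; empty list for an empty edge map. With `return_votes = TRUE`,
#'   a list with elements `peaks`, `votes`, and the bin geometry.
#' @export
hough_circles <- function(edges, r_range, bin_xy = 2, bin_r = 2,
                          top_k = 3, method = c("cone", "gradient"),
                          gx = NULL, gy = NULL, return_votes = FALSE) {
  method <- match.arg(method)
  assert_binary_mask(edges, "edges")
  h <- nrow(edges); w <- ncol(edges)
  diag_len <- sqrt(h^2 + w^2)
  if (r_range[1] <= 0 || r_range[2] > diag_len || r_range[1] > r_range[2])
    stop("invalid `r_range`")
  fg <- which(edges == 1L)
  r_bins <- seq(r_range[1], r_range[2], by = bin_r)
  nx <- ceiling(w / bin_xy); ny <- ceiling(h / bin_xy); nr <- length(r_bins)
  geom <- list(bin_xy = bin_xy, bin_r = bin_r, r_bins = r_bins,
               nx = nx, ny = ny, nr = nr)
  if (length(fg) == 0L) {
    out <- list()
    if (return_votes)
      return(c(list(peaks = out,
                    votes = array(0L, dim = c(ny, nx, nr))), geom))
    return(out)
  }
  py <- (fg - 1L) %% h + 1L
  px <- (fg - 1L) %/% h + 1L
  ncell <- ny * nx
  votes_vec <- integer(ncell * nr)
  if (method == "gradient") {
    if (is.null(gx) || is.null(gy))
      stop("`gradient` voting requires `gx` and `gy`")
    gxv <- gx[fg]; gyv <- gy[fg]
    gm <- sqrt(gxv^2 + gyv^2)
    ok <- gm > 1e-12
    ux <- gxv[ok] / gm[ok]; uy <- gyv[ok] / gm[ok]
    pxo <- px[ok]; pyo <- py[ok]
    for (ir in seq_len(nr)) {
      r <- r_bins[ir]
      cx <- c(pxo - r * ux, pxo + r * ux)
      cy <- c(pyo - r * uy, pyo + r * uy)
      bx <- ceiling(cx / bin_xy); by <- ceiling(cy / bin_xy)
      good <- bx >= 1 & bx <= nx & by >= 1 & by <= ny
      idx <- (ir - 1L) * ncell + (bx[good] - 1L) * ny + by[good]
      tab <- tabulate(idx, nbins = ncell * nr)
      votes_vec <- votes_vec + tab
    }
  } else {
    for (ir in seq_len(nr)) {
      r <- r_bins[ir]
      ntheta <- max(36L, ceiling(2.5 * pi * r / bin_xy))
      theta <- seq(0, 2 * pi, length.out = ntheta + 1L)[-1L]
      idx_all <- vector("list", ntheta)
      for (it in seq_len(ntheta)) {
        cx <- px - r * cos(theta[it])
        cy <- py - r * sin(theta[it])
        bx <- ceiling(cx / bin_xy); by <- ceiling(cy / bin_xy)
        good <- bx >= 1 & bx <= nx & by >= 1 & by <= ny
        idx_all[[it]] <- (bx[good] - 1L) * ny + by[good]
      }
      # one vote per (pixel, bin): duplicates from dense theta sampling
      # along the same bin are inherent to rasterized voting; keep raw tabs
      idx <- unlist(idx_all, use.names = FALSE)
      votes_vec[(ir - 1L) * ncell + seq_len(ncell)] <-
        votes_vec[(ir - 1L) * ncell + seq_len(ncell)] +
        tabulate(idx, nbins = ncell)
    }
  }
  votes <- array(votes_vec, dim = c(ny, nx, nr))
  peaks <- extract_hough_peaks(votes, geom, top_k)
  if (return_votes) c(list(peaks = peaks, votes = votes), geom) else peaks
}

# greedy peak extraction with NMS and centroid refinement
extract_hough_peaks <- function(votes, geom, top_k,
                                suppress = c(2L, 2L, 2L)) {
  dims <- dim(votes)
  cand <- which(votes > 0)
  if (length(cand) == 0L) return(list())
  vv <- votes[cand]
  by <- (cand - 1L) %% dims[1] + 1L
  bx <- ((cand - 1L) %/% dims[1]) %% dims[2] + 1L
  br <- (cand - 1L) %/% (dims[1] * dims[2]) + 1L
  ord <- order(-vv, -br, by, bx)
  taken <- matrix(numeric(0), ncol = 3)
  peaks <- list()
  for (i in ord) {
    if (length(peaks) >= top_k) break
    p <- c(by[i], bx[i], br[i])
    if (nrow(taken) > 0) {
      close_by <- abs(taken[, 1] - p[1]) <= suppress[1] &
        abs(taken[, 2] - p[2]) <= suppress[2] &
        abs(taken[, 3] - p[3]) <= suppress[3]
      if (any(close_by)) next
    }
    taken <- rbind(taken, p)
    peaks[[length(peaks) + 1L]] <-
      refine_peak(votes, p, geom, vv[i])
  }
  peaks
}

refine_peak <- function(votes, p, geom, vmax) {
  dims <- dim(votes)
  ys <- clamp((p[1] - 1):(p[1] + 1), 1, dims[1])
  xs <- clamp((p[2] - 1):(p[2] + 1), 1, dims[2])
  rs <- clamp((p[3] - 1):(p[3] + 1), 1, dims[3])
  nb <- votes[unique(ys), unique(xs), unique(rs), drop = FALSE]
  tot <- sum(nb)
  grid <- expand.grid(y = unique(ys), x = unique(xs), r = unique(rs))
  wy <- sum(grid$y * nb) / tot
  wx <- sum(grid$x * nb) / tot
  wr <- sum(grid$r * nb) / tot
  list(circle = circle(x0 = (wx - 0.5) * geom$bin_xy,
                       y0 = (wy - 0.5) * geom$bin_xy,
                       r = geom$r_bins[1] + (wr - 1) * geom$bin_r),
       votes = vmax)
}

#' Parameters of the dish localization cascade
#'
#' @param sigma Gaussian blur standard deviation before edge detection.
#' @param canny_percentiles hysteresis threshold percentiles.
#' @param bin_xy,bin_r Hough accumulator bin sizes in pixels.
#' @param dish_r_frac radius search band for the dish edge C1, as a
#'   fraction of `min(H, W)` (dishes roughly fill the frame).
#' @param inner_r_frac radius band, relative to `C1.r`, searched for the
#'   glass (C2) and water (C3) edges concentric with C1.
#' @param tol_center_frac concentricity tolerance relative to `C1.r`.
#' @param min_votes_frac a circle is accepted when its peak-bin votes
#'   exceed this fraction of its circumference in pixels; votes spread over
#'   neighboring bins, so the peak bin holds well under the full
#'   circumference even for a clean circle, while chance coincidences stay
#'   an order of magnitude lower.
#' @param hough_method `"gradient"` (fast, default) or `"cone"`.
#' @return List of class `"localize_params"`.
#' @export
localize_params <- function(sigma = 2.0,
                            canny_percentiles = c(0.70, 0.90),
                            bin_xy = 2, bin_r = 2,
                            dish_r_frac = c(0.43, 0.52),
                            inner_r_frac = c(0.70, 0.94),
                            tol_center_frac = 0.02,
                            min_votes_frac = 0.04,
                            hough_method = "gradient") {
  structure(list(sigma = sigma, canny_percentiles = canny_percentiles,
                 bin_xy = bin_xy, bin_r = bin_r,
                 dish_r_frac = dish_r_frac, inner_r_frac = inner_r_frac,
                 tol_center_frac = tol_center_frac,
                 min_votes_frac = min_votes_frac,
                 hough_method = hough_method),
            class = "localize_params")
}

# algebraic least-squares circle re-fit (Kasa) on edge pixels lying in a
# narrow annular window around a candidate circle; sub-pixel refinement
refit_circle <- function(edge_rows, edge_cols, ci, window = 2.5) {
  d <- sqrt((edge_rows - ci$y0)^2 + (edge_cols - ci$x0)^2)
  sel <- abs(d - ci$r) <= window
  if (sum(sel) < 8) return(ci)
  x <- edge_cols[sel]; y <- edge_rows[sel]
  a_mat <- cbind(2 * x, 2 * y, 1)
  rhs <- x^2 + y^2
  sol <- tryCatch(qr.solve(a_mat, rhs), error = function(e) NULL)
  if (is.null(sol)) return(ci)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (r2 <= 0) return(ci)
  circle(x0 = sol[1], y0 = sol[2], r = sqrt(r2))
}

# radii of circles concentric with a known center: peaks of the smoothed
# 1-px histogram of edge-pixel distances to the center, strongest first
concentric_radii <- function(edge_rows, edge_cols, center_xy, r_lo, r_hi,
                             min_count_frac = 0.15, min_sep = 6) {
  d <- sqrt((edge_cols - center_xy[1])^2 + (edge_rows - center_xy[2])^2)
  breaks <- seq(floor(r_lo) - 2, ceiling(r_hi) + 2, by = 1)
  cnt <- tabulate(findInterval(d, breaks), length(breaks))
  sm <- stats::filter(cnt, c(1, 2, 3, 2, 1) / 9, sides = 2)
  sm[is.na(sm)] <- 0
  mid <- breaks + 0.5
  ok <- mid >= r_lo & mid <= r_hi
  peaks <- numeric(0); support <- numeric(0)
  sm_work <- as.numeric(sm)
  repeat {
    cand <- which(ok & sm_work > 0)
    if (length(cand) == 0L) break
    i <- cand[which.max(sm_work[cand])]
    r_est <- mid[i]
    if (sm_work[i] < min_count_frac * 2 * pi * r_est / 3) break
    peaks <- c(peaks, r_est); support <- c(support, sm_work[i])
    sm_work[abs(mid - r_est) < min_sep] <- 0
  }
  list(r = peaks, support = support)
}

#' Localize the Petri dish and its reflection-prone bezel
#'
#' Pipeline: grayscale conversion, Gaussian blur, Canny edge detection and
#' a single circle-Hough accumulator over the full radius search range.
#' The cascade then extracts C1 (dish edge) as the best-supported circle in
#' the dish radius band, C2 (glass edge) as the best circle concentric with
#' C1 in the `c2_frac` band, and C3 (water edge) as the best concentric
#' circle below C2. The bezel mask is the annulus strictly between C3 and
#' C1 (distances measured from the C1 center). C2 is informative only:
#' failing to find it does not invalidate the localization, but a missing
#' C1 or C3 sets `found = FALSE` with an empty mask, which drives the
#' fallback branch of the hybrid counting rule.
#'
#' @param image RGB array or grayscale matrix.
#' @param params a [localize_params()].
#' @return Object of class `"dish_localization"`: list with `c1`, `c2`,
#'   `c3` ([circle()] or `NULL`), `bezel_mask` (binary H x W), `found`.
#' @export
localize_dish <- function(image, params = localize_params()) {
  gray <- if (is.matrix(image)) image
          else (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  h <- nrow(gray); w <- ncol(gray)
  not_found <- structure(list(c1 = NULL, c2 = NULL, c3 = NULL,
                              bezel_mask = matrix(0L, h, w), found = FALSE),
                         class = "dish_localization")
  blurred <- gaussian_blur(gray, blur_config(params$sigma))
  ce <- canny_edges(blurred, percentiles = params$canny_percentiles)
  if (sum(ce$edges) == 0L) return(not_found)
  s <- min(h, w)
  r_lo <- params$inner_r_frac[1] * params$dish_r_frac[1] * s
  r_hi <- params$dish_r_frac[2] * s
  hh <- hough_circles(ce$edges, c(r_lo, r_hi),
                      bin_xy = params$bin_xy, bin_r = params$bin_r,
                      top_k = 1, method = params$hough_method,
                      gx = ce$gx, gy = ce$gy, return_votes = TRUE)
  geom <- hh[c("bin_xy", "bin_r", "r_bins", "nx", "ny", "nr")]
  votes <- hh$votes
  accept <- function(pk) {
    !is.null(pk) && pk$votes >= params$min_votes_frac * 2 * pi * pk$circle$r
  }
  # C1: best-supported circle in the dish radius band (any center)
  dish_rsel <- which(geom$r_bins >= params$dish_r_frac[1] * s &
                     geom$r_bins <= r_hi)
  if (length(dish_rsel) == 0L) return(not_found)
  sub <- votes[, , dish_rsel, drop = FALSE]
  if (max(sub) == 0) return(not_found)
  idx <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  c1_pk <- refine_peak(votes, c(idx[1], idx[2], dish_rsel[idx[3]]),
                       geom, max(sub))
  if (!accept(c1_pk)) return(not_found)
  efg <- which(ce$edges == 1L)
  erow <- (efg - 1L) %% h + 1L
  ecol <- (efg - 1L) %/% h + 1L
  c1 <- refit_circle(erow, ecol, c1_pk$circle)
  # inner circles share the C1 center: their radii are peaks of the radial
  # edge-distance histogram, read outer -> inner (glass first, then water)
  inner <- concentric_radii(erow, ecol, c(c1$x0, c1$y0),
                            params$inner_r_frac[1] * c1$r,
                            params$inner_r_frac[2] * c1$r)
  radii <- sort(inner$r, decreasing = TRUE)
  refit_inner <- function(r_est) {
    ci <- circle(c1$x0, c1$y0, r_est)
    for (it in 1:3) ci <- refit_circle(erow, ecol, ci, window = 2)
    if (abs(ci$r - r_est) > 3) ci <- circle(c1$x0, c1$y0, r_est)
    ci
  }
  circles <- lapply(radii, refit_inner)
  # histogram shoulders of one physical ring refit to the same circle:
  # keep the first occurrence of each distinct radius
  if (length(circles) > 1) {
    keep <- rep(TRUE, length(circles))
    for (i in seq_along(circles)[-1]) {
      ri <- circles[[i]]$r
      prev <- vapply(circles[seq_len(i - 1)][keep[seq_len(i - 1)]],
                     function(ci) ci$r, numeric(1))
      if (any(abs(prev - ri) < 8.5)) keep[i] <- FALSE
    }
    circles <- circles[keep]
    circles <- circles[order(-vapply(circles, function(ci) ci$r,
                                     numeric(1)))]
  }
  if (length(circles) >= 2) {
    c2 <- circles[[1]]
    c3 <- circles[[2]]
  } else if (length(circles) == 1) {
    c2 <- NULL
    c3 <- circles[[1]]
  } else {
    c2 <- c3 <- NULL
  }
  if (is.null(c3)) {
    out <- not_found
    out$c1 <- c1; out$c2 <- c2
    return(out)
  }
  d <- pixel_dist(h, w, c1$y0, c1$x0)
  bezel <- matrix(0L, h, w)
  bezel[d > c3$r & d <= c1$r] <- 1L
  structure(list(c1 = c1, c2 = c2, c3 = c3, bezel_mask = bezel,
                 found = TRUE),
            class = "dish_localization")
}

#' @export
print.dish_localization <- function(x, ...) {
  if (!x$found) {
    cat("dish_localization: not found\n")
  } else {
    cat(sprintf(
      "dish_localization: C1 r=%.1f, C2 r=%s, C3 r=%.1f, bezel %d px\n",
      x$c1$r, if (is.null(x$c2)) "NA" else sprintf("%.1f", x$c2$r),
      x$c3$r, sum(x$bezel_mask)))
  }
  invisible(x)
}
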