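# Region-level cleanup of predicted masks and connected-component counting.

# igraph-based connected-component labeling with explicit connectivity
label_components <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask == 1)
  labels <- matrix(0L, h, w)
  if (length(fg) == 0L)
    return(list(labels = labels, n = 0L))
  id <- integer(h * w)
  id[fg] <- seq_along(fg)
  offsets <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8)
    offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  else if (connectivity != 4)
    stop("`connectivity` must be 4 or 8")
  rows <- (fg - 1L) %% h + 1L
  cols <- (fg - 1L) %/% h + 1L
  edges <- integer(0)
  for (off in offsets) {
    r2 <- rows + off[1]; c2 <- cols + off[2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    nb <- (c2[ok] - 1L) * h + r2[ok]
    ok2 <- id[nb] > 0L
    if (any(ok2))
      edges <- c(edges, rbind(id[fg[ok]][ok2], id[nb][ok2]))
  }
  g <- igraph::make_graph(edges = edges, n = length(fg), directed = FALSE)
  memb <- igraph::components(g)$membership
  # relabel 1..n in first-pixel order for determinism
  first <- tapply(seq_along(fg), memb, min)
  ord <- rank(first)
  labels[fg] <- as.integer(ord[memb])
  list(labels = labels, n = max(labels))
}

#' Label and count connected foreground regions
#'
#' Counts maximal connected components of a binary mask under 4- or
#' 8-neighbor adjacency. No minimum-size filtering is applied by default;
#' `min_area` optionally drops regions below a pixel-area threshold (the
#' interactive-use slider).
#'
#' @param mask binary H x W matrix.
#' @param connectivity 4 or 8 (default 8).
#' @param min_area drop regions with fewer pixels than this (default 0,
#'   i.e. keep everything).
#' @return An object of class `"labeled_regions"`: list with `labels`
#'   (integer H x W label map, 0 = background), `n_regions`, and `regions`
#'   (data frame: `label`, `area`, `centroid_r`, `centroid_c`, `rmin`,
#'   `cmin`, `rmax`, `cmax`).
#' @export
count_regions <- function(mask, connectivity = 8, min_area = 0) {
  assert_binary_mask(mask)
  lab <- label_components(mask, connectivity)
  labels <- lab$labels
  n <- lab$n
  if (n > 0L) {
    fg <- which(labels > 0L)
    lv <- labels[fg]
    h <- nrow(mask)
    rows <- (fg - 1L) %% h + 1L
    cols <- (fg - 1L) %/% h + 1L
    area <- tabulate(lv, n)
    regions <- data.frame(
      label = seq_len(n),
      area = area,
      centroid_r = as.numeric(tapply(rows, lv, mean)),
      centroid_c = as.numeric(tapply(cols, lv, mean)),
      rmin = as.integer(tapply(rows, lv, min)),
      cmin = as.integer(tapply(cols, lv, min)),
      rmax = as.integer(tapply(rows, lv, max)),
      cmax = as.integer(tapply(cols, lv, max)))
    if (min_area > 0) {
      drop <- regions$label[regions$area < min_area]
      if (length(drop)) {
        labels[labels %in% drop] <- 0L
        keep <- !(regions$label %in% drop)
        regions <- regions[keep, , drop = FALSE]
        relab <- integer(n); relab[regions$label] <- seq_len(nrow(regions))
        labels[labels > 0L] <- relab[labels[labels > 0L]]
        regions$label <- seq_len(nrow(regions))
        n <- nrow(regions)
      }
    }
  } else {
    regions <- data.frame(label = integer(), area = integer(),
                          centroid_r = numeric(), centroid_c = numeric(),
                          rmin = integer(), cmin = integer(),
                          rmax = integer(), cmax = integer())
  }
  structure(list(labels = labels, n_regions = n, regions = regions),
            class = "labeled_regions")
}

#' @export
print.labeled_regions <- function(x, ...) {
  cat(sprintf("labeled_regions: %d region(s)\n", x$n_regions))
  invisible(x)
}

# pixels of the filled convex hull of a point set (pixel centers),
# including boundary points; returns an index matrix (row, col)
fill_convex_hull <- function(rows, cols, h, w) {
  pts <- cbind(cols, rows)                       # (x, y)
  hull <- grDevices::chull(pts)
  v <- pts[hull, , drop = FALSE]                 # clockwise order from chull
  nv <- nrow(v)
  if (nv <= 2L) return(cbind(rows, cols))
  r1 <- max(1L, min(rows)); r2 <- min(h, max(rows))
  c1 <- max(1L, min(cols)); c2 <- min(w, max(cols))
  gr <- rep(r1:r2, times = c2 - c1 + 1L)
  gc <- rep(c1:c2, each = r2 - r1 + 1L)
  inside <- rep(TRUE, length(gr))
  tol <- 1e-9
  for (i in seq_len(nv)) {                       # point-in-convex-polygon
    j <- if (i == nv) 1L else i + 1L
    ex <- v[j, 1] - v[i, 1]; ey <- v[j, 2] - v[i, 2]
    cr <- ex * (gr - v[i, 2]) - ey * (gc - v[i, 1])
    inside <- inside & (cr <= tol)               # chull is clockwise in (x,y)
  }
  cbind(gr[inside], gc[inside])
}

#' Replace each connected region by its filled convex hull
#'
#' Smooths exterior region contours: every connected component is replaced
#' by the set of pixels whose centers fall inside (or on) the convex hull
#' of the component's pixel centers. Hulls of distinct regions that touch
#' or overlap merge into one region; the operation is repeated until the
#' mask is stable, so the result is idempotent and a superset of the
#' input.
#'
#' @param mask binary H x W matrix.
#' @param connectivity adjacency used to delineate regions (default 8).
#' @return Binary H x W matrix.
#' @export
convex_hull_regions <- function(mask, connectivity = 8) {
  assert_binary_mask(mask)
  repeat {
    out <- hull_pass(mask, connectivity)
    if (identical(out, mask)) return(out)
    mask <- out
  }
}

hull_pass <- function(mask, connectivity) {
  lab <- label_components(mask, connectivity)
  if (lab$n == 0L) return(mask)
  out <- mask
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(lab$labels > 0L)
  lv <- lab$labels[fg]
  rows <- (fg - 1L) %% h + 1L
  cols <- (fg - 1L) %/% h + 1L
  for (k in seq_len(lab$n)) {
    sel <- lv == k
    out[fill_convex_hull(rows[sel], cols[sel], h, w)] <- 1L
  }
  out
}

#' Fill interior holes of foreground regions
#'
#' Background components not connected to the image border become
#' foreground. Idempotent and extensive (output is a superset of the
#' input).
#'
#' @param mask binary H x W matrix.
#' @return Binary H x W matrix.
#' @export
fill_holes <- function(mask) {
  assert_binary_mask(mask)
  filled <- EBImage::fillHull(mask)
  m <- matrix(as.integer(filled > 0), nrow(mask), ncol(mask))
  m
}
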