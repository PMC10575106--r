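# Ground-truth construction: the full-resolution segmentation target and
# the coarse centroid indicator consumed by the bottleneck alignment loss.

#' Build the full-resolution segmentation target from colony annotations
#'
#' Each colony contributes a filled disc centered on its centroid with
#' radius one tenth of the smaller bounding-box side (at least 1 px);
#' overlapping discs union. This disc-drawing convention replaces blurred
#' density-map targets: the target stays a crisp binary map.
#'
#' @param colonies data frame with columns `row`, `col` (centroids) and
#'   either `radius` or bounding-box columns `rmin`, `cmin`, `rmax`, `cmax`;
#'   an optional logical `is_reflection` column excludes reflections.
#' @param h,w output map size in pixels.
#' @param radius_divisor divisor applied to the minimal bounding-box side
#'   (default 10, i.e. one tenth).
#' @return Integer H x W matrix of 0/1 (class `"out_map"` attribute-free).
#' @export
build_yout <- function(colonies, h, w, radius_divisor = 10) {
  m <- matrix(0L, h, w)
  if (is.null(colonies) || nrow(colonies) == 0L) return(m)
  if (!is.null(colonies$is_reflection))
    colonies <- colonies[!colonies$is_reflection, , drop = FALSE]
  for (i in seq_len(nrow(colonies))) {
    row0 <- colonies$row[i]; col0 <- colonies$col[i]
    if (row0 < 1 || row0 > h || col0 < 1 || col0 > w)
      stop("colony centroid outside image bounds")
    if (!is.null(colonies$rmin)) {
      bh <- colonies$rmax[i] - colonies$rmin[i]
      bw <- colonies$cmax[i] - colonies$cmin[i]
    } else {
      bh <- bw <- 2 * colonies$radius[i]
    }
    if (bh <= 0 || bw <= 0) stop("bounding box must have positive size")
    rad <- max(1, round(min(bh, bw) / radius_divisor))
    px <- disc_mask_pixels(h, w, row0, col0, rad)
    m[px] <- 1L
  }
  m
}

#' Build the coarse centroid indicator map for the bottleneck loss
#'
#' Maps every non-reflection colony centroid from the H x W input grid onto
#' an m x m grid: the cell under the centroid is activated. Centroids
#' sharing a cell leave it at 1 (the indicator stays binary). Cell
#' assignment is floor binning of `(coordinate - 1) * m / extent`, 0-based
#' internally, returned as a 1-based m x m matrix.
#'
#' @param colonies data frame with `row`, `col` and optional
#'   `is_reflection` (reflections are excluded).
#' @param h,w input image size; `m` must divide both.
#' @param m coarse grid size in cells (e.g. 64 for 1024-px inputs with five
#'   resolution levels).
#' @return Integer m x m matrix of 0/1.
#' @export
build_ymid <- function(colonies, h, w, m) {
  if (h %% m != 0L || w %% m != 0L)
    stop("`m` must divide both `h` and `w` (ambiguous cell geometry otherwise)")
  grid <- matrix(0L, m, m)
  if (is.null(colonies) || nrow(colonies) == 0L) return(grid)
  if (!is.null(colonies$is_reflection))
    colonies <- colonies[!colonies$is_reflection, , drop = FALSE]
  if (nrow(colonies) == 0L) return(grid)
  if (any(colonies$row < 1 | colonies$row > h |
          colonies$col < 1 | colonies$col > w))
    stop("colony centroid outside image bounds")
  ri <- pmin(floor((colonies$row - 1) * m / h) + 1L, m)
  ci <- pmin(floor((colonies$col - 1) * m / w) + 1L, m)
  grid[cbind(ri, ci)] <- 1L
  grid
}
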