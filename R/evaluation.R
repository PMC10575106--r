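# Count-level evaluation: MAE and sMAPE, stratified reporting, and the
# counting-mode ablation table.

#' Mean absolute error of predicted counts
#'
#' `MAE = mean(|n_i - npred_i|)`, reported in colony-count units.
#' Predictions may be fractional (the hybrid rule halves bezel counts).
#'
#' @param true_counts,pred_counts equal-length nonnegative vectors.
#' @return A single nonnegative number.
#' @export
mae <- function(true_counts, pred_counts) {
  check_count_vectors(true_counts, pred_counts)
  mean(abs(true_counts - pred_counts))
}

#' Symmetric mean absolute percentage error of predicted counts
#'
#' `sMAPE = (100 / N) * sum(|n_i - npred_i| / |n_i + npred_i|)` in
#' percent; pairs with `n_i + npred_i = 0` contribute 0 (perfect
#' agreement). Bounded in \[0, 100\] for nonnegative counts.
#'
#' @inheritParams mae
#' @return A percentage in \[0, 100\].
#' @export
smape <- function(true_counts, pred_counts) {
  check_count_vectors(true_counts, pred_counts)
  s <- abs(true_counts + pred_counts)
  term <- ifelse(s == 0, 0, abs(true_counts - pred_counts) / s)
  100 * mean(term)
}

check_count_vectors <- function(a, b) {
  if (length(a) == 0L) stop("empty count vectors")
  if (length(a) != length(b)) stop("count vectors differ in length")
  if (any(a < 0) || any(b < 0)) stop("counts must be nonnegative")
  invisible(NULL)
}

#' Metrics over all images and over the low-count stratum
#'
#' Reports MAE and sMAPE over every image and, separately, over images
#' whose true count falls strictly below `threshold` (errors are more
#' consequential on sparse plates).
#'
#' @inheritParams mae
#' @param threshold stratum cut-off on the true count (default 100).
#' @return Object of class `"metrics_report"`: list with components `all`
#'   and `under` (each with `mae`, `smape`, `n_images`, `empty`), the
#'   `threshold`, and `per_image` (data frame with `true`, `pred`,
#'   `abs_error`, `in_stratum`).
#' @export
stratified_report <- function(true_counts, pred_counts, threshold = 100) {
  check_count_vectors(true_counts, pred_counts)
  in_str <- true_counts < threshold
  one <- function(sel) {
    if (!any(sel))
      return(list(mae = NA_real_, smape = NA_real_, n_images = 0L,
                  empty = TRUE))
    list(mae = mae(true_counts[sel], pred_counts[sel]),
         smape = smape(true_counts[sel], pred_counts[sel]),
         n_images = sum(sel), empty = FALSE)
  }
  structure(list(
    all = one(rep(TRUE, length(true_counts))),
    under = one(in_str),
    threshold = threshold,
    per_image = data.frame(true = true_counts, pred = pred_counts,
                           abs_error = abs(true_counts - pred_counts),
                           in_stratum = in_str)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report (%d images): MAE %.3f, sMAPE %.3f%%\n",
              x$all$n_images, x$all$mae, x$all$smape))
  if (x$under$empty)
    cat(sprintf("  stratum true < %g: empty\n", x$threshold))
  else
    cat(sprintf("  stratum true < %g (%d images): MAE %.3f, sMAPE %.3f%%\n",
                x$threshold, x$under$n_images, x$under$mae, x$under$smape))
  invisible(x)
}

#' Counting-mode ablation table
#'
#' Evaluates the three counting modes (naive segmentation-only counting,
#' uniform counting inside the dish, and the hybrid bezel-halving rule) on
#' identical masks and localizations, reporting MAE and sMAPE per mode.
#' Images whose localization failed use the naive fallback in every mode
#' and are flagged.
#'
#' @param masks list of post-processed binary masks.
#' @param localizations list of [localize_dish()] results (same length).
#' @param true_counts vector of ground-truth counts.
#' @param connectivity region connectivity.
#' @return Data frame with one row per metric (`mae`, `smape`) and one
#'   column per mode (`naive`, `uniform`, `hybrid`); attributes
#'   `per_image` (counts per image and mode, with `used_fallback`) and
#'   `n_fallback`.
#' @export
ablation_table <- function(masks, localizations, true_counts,
                           connectivity = 8) {
  stopifnot(length(masks) == length(localizations),
            length(masks) == length(true_counts))
  rows <- lapply(seq_along(masks), function(i) {
    ac <- ablation_count(masks[[i]], localizations[[i]], connectivity)
    data.frame(image = i, true = true_counts[i],
               naive = ac$naive$n, uniform = ac$uniform$n,
               hybrid = ac$hybrid$n,
               used_fallback = ac$hybrid$used_fallback)
  })
  per_image <- do.call(rbind, rows)
  tab <- data.frame(
    metric = c("mae", "smape"),
    naive = c(mae(per_image$true, per_image$naive),
              smape(per_image$true, per_image$naive)),
    uniform = c(mae(per_image$true, per_image$uniform),
                smape(per_image$true, per_image$uniform)),
    hybrid = c(mae(per_image$true, per_image$hybrid),
               smape(per_image$true, per_image$hybrid)))
  attr(tab, "per_image") <- per_image
  attr(tab, "n_fallback") <- sum(per_image$used_fallback)
  tab
}
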