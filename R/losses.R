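# Training losses. Probability maps and one-hot targets are H x W x 2
# arrays (class 1 = background, class 2 = foreground); the bottleneck
# alignment loss consumes plain m x m matrices.

#' Loss configuration
#'
#' @param epsilon normalization constant guarding the dice denominators.
#' @param tversky_alpha,tversky_beta false-negative and false-positive
#'   weights of the Tversky index; 0.5/0.5 reduces it to a smoothed dice.
#' @param dice_variant `"as_printed"` uses a product of L1 norms in the
#'   denominator; `"standard"` the usual sum form.
#' @param combination objective used by [loss_combined()]:
#'   `"tversky_ce"` (Tversky + cross-entropy, the single-loss objective),
#'   `"tversky_ce_mid"` (adds the bottleneck alignment term; the multi-loss
#'   objective), or `"eq_sum"` (bottleneck + cross-entropy + dice).
#' @param ce_reduction `"sum"` (entry-wise norm over all pixels) or
#'   `"mean"` (per-pixel average; keeps the term on the same O(1) scale as
#'   the overlap losses during training).
#' @param mid_transform elementwise nonnegative transform applied to the
#'   channel-averaged bottleneck features before the alignment loss.
#' @return A list of class `"loss_config"`.
#' @export
loss_config <- function(epsilon = 1e-5,
                        tversky_alpha = 0.5, tversky_beta = 0.5,
                        dice_variant = c("as_printed", "standard"),
                        combination = c("tversky_ce", "tversky_ce_mid",
                                        "eq_sum"),
                        ce_reduction = c("sum", "mean"),
                        mid_transform = c("abs", "relu", "sigmoid")) {
  stopifnot(epsilon > 0, tversky_alpha >= 0, tversky_beta >= 0)
  structure(list(epsilon = epsilon,
                 tversky_alpha = tversky_alpha, tversky_beta = tversky_beta,
                 dice_variant = match.arg(dice_variant),
                 combination = match.arg(combination),
                 ce_reduction = match.arg(ce_reduction),
                 mid_transform = match.arg(mid_transform)),
            class = "loss_config")
}

check_two_class <- function(x, name) {
  if (length(dim(x)) != 3L || dim(x)[3] != 2L)
    stop(sprintf("`%s` must be an H x W x 2 array", name))
  invisible(x)
}

# dice/Tversky also accept a single-class map (H x W matrix or H x W x 1)
as_class_array <- function(x, name) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (length(dim(x)) != 3L || !(dim(x)[3] %in% c(1L, 2L)))
    stop(sprintf("`%s` must be H x W x 1 or H x W x 2", name))
  x
}

#' One-hot encode a binary mask into a two-class target
#' @param mask binary H x W matrix (1 = foreground).
#' @return H x W x 2 array; channel 1 background, channel 2 foreground.
#' @export
one_hot <- function(mask) {
  assert_binary_mask(mask)
  out <- array(0, dim = c(dim(mask), 2L))
  out[, , 1] <- 1 - mask
  out[, , 2] <- mask
  out
}

#' Bottleneck alignment loss
#'
#' Cosine-style alignment between the nonnegative channel-averaged
#' bottleneck feature map and the coarse centroid indicator:
#' `-sum(X * Y) / (||X||_F * ||Y||_F)`. Bounded in \[-1, 0\] for
#' nonnegative inputs, reaching -1 exactly when the maps are proportional
#' and 0 when their supports are disjoint. If either map is identically
#' zero the loss is defined as 0 (no gradient signal) with a warning.
#'
#' @param xmid nonnegative m x m matrix of averaged bottleneck features.
#' @param ymid binary m x m centroid indicator (see [build_ymid()]).
#' @return A single number in \[-1, 0\].
#' @export
loss_mid <- function(xmid, ymid) {
  if (!all(dim(xmid) == dim(ymid))) stop("`xmid` and `ymid` shapes differ")
  if (any(xmid < 0)) stop("`xmid` must be nonnegative")
  fx <- sqrt(sum(xmid^2)); fy <- sqrt(sum(ymid^2))
  if (fx == 0 || fy == 0) {
    warning("all-zero map in loss_mid; returning 0 (no gradient signal)")
    return(0)
  }
  -sum(xmid * ymid) / (fx * fy)
}

#' Cross-entropy loss over the two segmentation classes
#'
#' `-sum_c sum_pixels Y_c * log(X_c)` with probabilities clipped to
#' `[1e-7, 1]` for log stability. `reduction = "mean"` divides by the pixel
#' count.
#'
#' @param xout H x W x 2 array of class probabilities.
#' @param yout H x W x 2 one-hot target.
#' @param reduction `"sum"` or `"mean"`.
#' @return Nonnegative number.
#' @export
loss_ce <- function(xout, yout, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  check_two_class(xout, "xout"); check_two_class(yout, "yout")
  if (!all(dim(xout) == dim(yout))) stop("shape mismatch")
  p <- clamp(xout, 1e-7, 1)
  total <- -sum(yout * log(p))
  if (reduction == "mean") total <- total / prod(dim(xout)[1:2])
  total
}

#' Dice loss over the two segmentation classes
#'
#' The `"as_printed"` variant uses
#' `1 - sum_c |X_c * Y_c| / (|X_c| * |Y_c| + eps)` with a product of
#' entry-wise L1 norms in the denominator; `"standard"` the usual
#' `1 - sum_c 2 |X_c * Y_c| / (|X_c| + |Y_c| + eps)`.
#'
#' @inheritParams loss_ce
#' @param config a [loss_config()] (supplies `dice_variant` and `epsilon`).
#' @return A single number.
#' @export
loss_dice <- function(xout, yout, config = loss_config()) {
  xout <- as_class_array(xout, "xout"); yout <- as_class_array(yout, "yout")
  if (!all(dim(xout) == dim(yout))) stop("shape mismatch")
  eps <- config$epsilon
  acc <- 0
  for (ch in seq_len(dim(xout)[3])) {
    x <- xout[, , ch]; y <- yout[, , ch]
    inter <- sum(abs(x * y))
    if (config$dice_variant == "as_printed")
      acc <- acc + inter / (sum(abs(x)) * sum(abs(y)) + eps)
    else
      acc <- acc + 2 * inter / (sum(abs(x)) + sum(abs(y)) + eps)
  }
  1 - acc
}

#' Tversky loss on soft class counts
#'
#' Per class, `TI = (TP + s) / (TP + alpha*FN + beta*FP + s)` on soft
#' counts with smoothing `s`; the loss is the mean over classes of
#' `1 - TI`. With `alpha = beta = 0.5` this is algebraically a smoothed
#' dice loss.
#'
#' @inheritParams loss_ce
#' @param alpha false-negative weight.
#' @param beta false-positive weight.
#' @param smooth smoothing constant.
#' @return A single number in \[0, 1\].
#' @export
loss_tversky <- function(xout, yout, alpha = 0.5, beta = 0.5,
                         smooth = 1e-5) {
  xout <- as_class_array(xout, "xout"); yout <- as_class_array(yout, "yout")
  if (!all(dim(xout) == dim(yout))) stop("shape mismatch")
  nc <- dim(xout)[3]
  acc <- 0
  for (ch in seq_len(nc)) {
    x <- xout[, , ch]; y <- yout[, , ch]
    tp <- sum(x * y); fn <- sum((1 - x) * y); fp <- sum(x * (1 - y))
    denom <- tp + alpha * fn + beta * fp + smooth
    if (denom == 0) {
      warning("degenerate Tversky denominator; contributing 0")
      next
    }
    acc <- acc + (1 - (tp + smooth) / denom)
  }
  acc / nc
}

#' Combined training objective with per-term breakdown
#'
#' `"tversky_ce"` returns Tversky + cross-entropy (single-loss objective);
#' `"tversky_ce_mid"` adds the bottleneck alignment term (the multi-loss
#' objective); `"eq_sum"` returns alignment + cross-entropy + dice. Terms
#' are summed with no weighting coefficients.
#'
#' @inheritParams loss_dice
#' @param xmid,ymid bottleneck maps (ignored by `"tversky_ce"`).
#' @return List with `total` and named vector `terms` summing to `total`.
#' @export
loss_combined <- function(xmid, xout, ymid, yout, config = loss_config()) {
  terms <- switch(
    config$combination,
    tversky_ce = c(
      tversky = loss_tversky(xout, yout, config$tversky_alpha,
                             config$tversky_beta),
      ce = loss_ce(xout, yout, config$ce_reduction)),
    tversky_ce_mid = c(
      mid = loss_mid(xmid, ymid),
      tversky = loss_tversky(xout, yout, config$tversky_alpha,
                             config$tversky_beta),
      ce = loss_ce(xout, yout, config$ce_reduction)),
    eq_sum = c(
      mid = loss_mid(xmid, ymid),
      ce = loss_ce(xout, yout, config$ce_reduction),
      dice = loss_dice(xout, yout, config)),
    stop("unknown loss combination: ", config$combination))
  list(total = sum(terms), terms = terms)
}
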