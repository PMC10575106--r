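# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Run code under a temporary RNG seed, restoring global RNG state after
#' @noRd
with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Matrix of distances from every pixel center to a point
#'
#' Pixel (i, j) has center at row i, column j (1-based).
#' @noRd
pixel_dist <- function(h, w, row0, col0) {
  dr <- (seq_len(h) - row0)^2
  dc <- (seq_len(w) - col0)^2
  sqrt(outer(dr, dc, `+`))
}

assert_binary_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask)) stop(sprintf("`%s` must be a matrix", arg))
  u <- unique(as.vector(mask))
  if (!all(u %in% c(0, 1)))
    stop(sprintf("`%s` must be binary (0/1); found other values", arg))
  invisible(mask)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
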