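#' Circle in pixel coordinates
#'
#' @param x0 column of the center (1-based pixel centers).
#' @param y0 row of the center.
#' @param r radius in pixels, positive.
#' @return An object of class `"circle"`: a list with `x0`, `y0`, `r`.
#' @export
circle <- function(x0, y0, r) {
  stopifnot(is_scalar_num(x0), is_scalar_num(y0), is_scalar_num(r), r > 0)
  structure(list(x0 = x0, y0 = y0, r = r), class = "circle")
}

#' @export
print.circle <- function(x, ...) {
  cat(sprintf("circle: center (x0 = %.2f, y0 = %.2f), r = %.2f px\n",
              x$x0, x$y0, x$r))
  invisible(x)
}

#' Configuration for the synthetic dish-scene generator
#'
#' The generator renders a bright circular Petri dish on a dark background.
#' Three concentric brightness transitions mark the dish edge, the glass edge
#' and the water edge; colonies are anti-aliased bright discs inside the
#' water zone; a configurable fraction of colonies close to the water edge
#' receives a dimmed mirror copy across the glass circle. Both members of
#' such a pair lie in the bezel annulus between the water and dish edges,
#' so a perfect segmenter sees the colony twice -- the double-counting
#' failure mode the hybrid counting rule corrects by halving the bezel
#' count.
#'
#' @param height,width image size in pixels.
#' @param count_range integer range (inclusive) for the number of colonies,
#'   or a single fixed count.
#' @param radius_range colony radius range in pixels; default scales with
#'   resolution as `c(0.010, 0.022) * min(height, width)`.
#' @param intensity_range colony peak intensity range, in (0, 1].
#' @param reflection_prob probability that an eligible near-edge colony
#'   produces a mirrored reflection in the bezel.
#' @param reflection_dim multiplicative attenuation of reflections
#'   (default 1: a full-strength mirror image, locally indistinguishable
#'   from its parent colony -- the regime the bezel-halving rule targets).
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param non_overlap if `TRUE` (default), colonies are rejection-sampled so
#'   discs do not touch, keeping the count/connected-component identity exact.
#' @param dish_frac dish radius as a fraction of `min(height, width)`.
#' @param glass_frac,water_frac glass and water radii as fractions of the
#'   dish radius (`water_frac < glass_frac < 1`).
#' @param bezel_colony_frac fraction of colonies placed in the bezel strip
#'   between the water and glass edges (when their radius fits); these are
#'   the reflection-eligible colonies.
#' @param falloff radial intensity falloff inside a colony (0 = flat disc).
#' @param channel_gain per-channel RGB gain applied to the dish area, giving
#'   the agar a slight amber cast.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(height = 512L, width = 512L,
                             count_range = c(5L, 30L),
                             radius_range = NULL,
                             intensity_range = c(0.70, 0.95),
                             reflection_prob = 0.8,
                             reflection_dim = 1.0,
                             noise_sd = 0.02,
                             non_overlap = TRUE,
                             dish_frac = 0.45,
                             glass_frac = 0.88,
                             water_frac = 0.78,
                             bezel_colony_frac = 0.25,
                             falloff = 0.3,
                             channel_gain = c(1.0, 0.96, 0.88)) {
  if (length(count_range) == 1L) count_range <- rep(count_range, 2L)
  if (is.null(radius_range))
    radius_range <- pmax(1, c(0.010, 0.022) * min(height, width))
  cfg <- list(height = as.integer(height), width = as.integer(width),
              count_range = as.integer(count_range),
              radius_range = radius_range,
              intensity_range = intensity_range,
              reflection_prob = reflection_prob,
              reflection_dim = reflection_dim,
              noise_sd = noise_sd, non_overlap = isTRUE(non_overlap),
              dish_frac = dish_frac, glass_frac = glass_frac,
              water_frac = water_frac,
              bezel_colony_frac = bezel_colony_frac, falloff = falloff,
              channel_gain = channel_gain)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  with(cfg, {
    if (height < 64L || width < 64L) stop("image must be at least 64x64")
    if (any(count_range < 0L) || count_range[1] > count_range[2])
      stop("invalid `count_range`")
    if (radius_range[1] < 1) stop("colony radius must be >= 1 px")
    dish_r <- dish_frac * min(height, width)
    if (radius_range[2] >= dish_r)
      stop("colony radius exceeds the dish radius: invalid configuration")
    if (!(water_frac < glass_frac && glass_frac < 1))
      stop("need water_frac < glass_frac < 1")
    if (reflection_prob < 0 || reflection_prob > 1)
      stop("`reflection_prob` must be in [0, 1]")
  })
  invisible(cfg)
}

# mirror a point across the glass circle along the radial direction
mirror_across_glass <- function(row, col, center_row, center_col, glass_r) {
  dr <- row - center_row; dc <- col - center_col
  d <- sqrt(dr^2 + dc^2)
  if (d < 1e-9) return(c(center_row, center_col))
  d2 <- 2 * glass_r - d
  c(center_row + dr / d * d2, center_col + dc / d * d2)
}

# paint one anti-aliased disc onto a canvas; returns modified canvas
paint_disc <- function(canvas, row0, col0, rad, peak, falloff) {
  h <- nrow(canvas); w <- ncol(canvas)
  r1 <- max(1L, floor(row0 - rad - 2)); r2 <- min(h, ceiling(row0 + rad + 2))
  c1 <- max(1L, floor(col0 - rad - 2)); c2 <- min(w, ceiling(col0 + rad + 2))
  rows <- r1:r2; cols <- c1:c2
  d <- sqrt(outer((rows - row0)^2, (cols - col0)^2, `+`))
  cov <- clamp(rad + 0.5 - d, 0, 1)                    # anti-aliased coverage
  inten <- peak * (1 - falloff * clamp(d / rad, 0, 1)^2)
  patch <- canvas[rows, cols]
  canvas[rows, cols] <- patch + cov * pmax(inten - patch, 0)
  canvas
}

disc_mask_pixels <- function(h, w, row0, col0, rad) {
  r1 <- max(1L, floor(row0 - rad)); r2 <- min(h, ceiling(row0 + rad))
  c1 <- max(1L, floor(col0 - rad)); c2 <- min(w, ceiling(col0 + rad))
  rows <- r1:r2; cols <- c1:c2
  d2 <- outer((rows - row0)^2, (cols - col0)^2, `+`)
  sel <- which(d2 <= rad^2, arr.ind = TRUE)
  cbind(rows[sel[, 1]], cols[sel[, 2]])
}

#' Generate a synthetic Petri dish scene with known ground truth
#'
#' Deterministic in `(config, seed)`: the same pair always yields the same
#' pixels and metadata. Most colonies are placed uniformly inside the water
#' zone; a configurable fraction grows in the bezel strip between the water
#' and glass edges (rejection-sampled to be non-overlapping when
#' `non_overlap` is set). Each bezel colony is mirrored across the glass
#' circle with probability `reflection_prob`, producing a dimmed twin, so
#' both members of the pair lie in the bezel annulus.
#'
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return An object of class `"dish_scene"`: a list with
#'   `image` (H x W x 3 array in \[0, 1\]), `dish`/`glass`/`water`
#'   ([circle()] ground truth), `colonies` and `reflections` (data frames
#'   with `id`, `row`, `col`, `radius`, `intensity`, `is_reflection`,
#'   `parent_id`), `truth_mask` (colonies only), `visible_mask`
#'   (colonies plus reflections), `true_count`, `seed`, and `config`.
#' @export
generate_scene <- function(config = generator_config(), seed = 1L) {
  validate_generator_config(config)
  with_local_seed(seed, {
    h <- config$height; w <- config$width
    dish_r <- config$dish_frac * min(h, w)
    cy <- h / 2 + runif(1, -4, 4)
    cx <- w / 2 + runif(1, -4, 4)
    glass_r <- config$glass_frac * dish_r
    water_r <- config$water_frac * dish_r
    # glass/water centers jittered < 1 px off the dish center
    gcy <- cy + runif(1, -0.8, 0.8); gcx <- cx + runif(1, -0.8, 0.8)
    wcy <- cy + runif(1, -0.8, 0.8); wcx <- cx + runif(1, -0.8, 0.8)

    d_dish  <- pixel_dist(h, w, cy, cx)
    d_glass <- pixel_dist(h, w, gcy, gcx)
    d_water <- pixel_dist(h, w, wcy, wcx)

    # concentric brightness zones: dark background, uniform bezel zone,
    # brighter interior; the glass edge shows as a thin dark ring so the
    # two bezel sub-bands are indistinguishable by local context
    base <- matrix(0.08, h, w)
    base[d_dish <= dish_r] <- 0.45          # bezel (water..dish)
    base[d_water <= water_r] <- 0.58        # interior (agar + water)
    ring <- clamp(1.7 - abs(d_glass - glass_r), 0, 1)
    base <- base - 0.15 * ring * (d_dish <= dish_r)

    n <- if (config$count_range[1] == config$count_range[2])
      config$count_range[1]
    else sample(config$count_range[1]:config$count_range[2], 1L)

    colonies <- data.frame(id = integer(), row = numeric(), col = numeric(),
                           radius = numeric(), intensity = numeric(),
                           is_reflection = logical(), parent_id = integer())
    placed <- 0L; attempts <- 0L
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > 400L * max(n, 1L))
        stop("rejection sampling failed to place all colonies; ",
             "reduce the count or radius range")
      rad <- runif(1, config$radius_range[1], config$radius_range[2])
      # a fraction of colonies grows in the bezel strip between the water
      # and glass edges (the agar extends to the wall); these are the
      # colonies whose reflections double the apparent bezel count
      strip_lo <- water_r + rad + 1
      strip_hi <- glass_r - rad - 1
      in_bezel <- runif(1) < config$bezel_colony_frac && strip_hi > strip_lo
      th <- runif(1, 0, 2 * pi)
      if (in_bezel) {
        rr <- runif(1, strip_lo, strip_hi)
        row0 <- gcy + rr * sin(th); col0 <- gcx + rr * cos(th)
      } else {
        rr <- (water_r - rad - 3) * sqrt(runif(1))
        row0 <- wcy + rr * sin(th); col0 <- wcx + rr * cos(th)
      }
      if (config$non_overlap && placed > 0L) {
        dd <- sqrt((colonies$row - row0)^2 + (colonies$col - col0)^2)
        if (any(dd < colonies$radius + rad + 2)) next
      }
      placed <- placed + 1L
      colonies[placed, ] <- list(placed, row0, col0, rad,
                                 runif(1, config$intensity_range[1],
                                       config$intensity_range[2]),
                                 FALSE, NA_integer_)
    }

    # reflections: bezel colonies are mirrored across the glass edge; the
    # mirror also lands in the bezel annulus, so a perfect segmenter sees
    # each such colony twice
    reflections <- colonies[0, ]
    if (n > 0L) {
      d_cent <- sqrt((colonies$row - gcy)^2 + (colonies$col - gcx)^2)
      eligible <- which(d_cent > water_r + colonies$radius &
                          d_cent < glass_r - colonies$radius &
                          d_cent > 2 * glass_r - dish_r + colonies$radius)
      for (i in eligible) {
        if (runif(1) > config$reflection_prob) next
        m <- mirror_across_glass(colonies$row[i], colonies$col[i],
                                 gcy, gcx, glass_r)
        k <- nrow(reflections) + 1L
        reflections[k, ] <- list(n + k, m[1], m[2], colonies$radius[i],
                                 colonies$intensity[i] * config$reflection_dim,
                                 TRUE, colonies$id[i])
      }
    }

    canvas <- base
    truth_mask <- matrix(0L, h, w)
    for (i in seq_len(nrow(colonies))) {
      canvas <- paint_disc(canvas, colonies$row[i], colonies$col[i],
                           colonies$radius[i], colonies$intensity[i],
                           config$falloff)
      px <- disc_mask_pixels(h, w, colonies$row[i], colonies$col[i],
                             colonies$radius[i])
      truth_mask[px] <- 1L
    }
    visible_mask <- truth_mask
    for (i in seq_len(nrow(reflections))) {
      canvas <- paint_disc(canvas, reflections$row[i], reflections$col[i],
                           reflections$radius[i], reflections$intensity[i],
                           config$falloff)
      px <- disc_mask_pixels(h, w, reflections$row[i], reflections$col[i],
                             reflections$radius[i])
      visible_mask[px] <- 1L
    }

    img <- array(0, dim = c(h, w, 3L))
    on_dish <- d_dish <= dish_r
    for (ch in 1:3) {
      plane <- canvas
      plane[on_dish] <- plane[on_dish] * config$channel_gain[ch]
      plane <- plane + rnorm(h * w, 0, config$noise_sd)
      img[, , ch] <- clamp(plane, 0, 1)
    }

    structure(list(
      image = img,
      dish = circle(cx, cy, dish_r),
      glass = circle(gcx, gcy, glass_r),
      water = circle(wcx, wcy, water_r),
      colonies = colonies, reflections = reflections,
      truth_mask = truth_mask, visible_mask = visible_mask,
      true_count = nrow(colonies), seed = as.integer(seed),
      config = config), class = "dish_scene")
  })
}

#' @export
print.dish_scene <- function(x, ...) {
  cat(sprintf(
    "dish_scene %dx%d: %d colonies (+%d reflections), dish r = %.1f px, seed %d\n",
    dim(x$image)[1], dim(x$image)[2], x$true_count, nrow(x$reflections),
    x$dish$r, x$seed))
  invisible(x)
}

#' Write per-colony annotations for a scene as JSON
#'
#' Emits one record per rendered blob (colonies and reflections) with its
#' bounding box and centroid, plus the ground-truth count of true colonies.
#' Round-trips losslessly through [read_annotations()].
#'
#' @param scene a [generate_scene()] result.
#' @param path output file path.
#' @param image_name name stored in the `"image"` field.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(scene, path, image_name = "scene.png") {
  stopifnot(inherits(scene, "dish_scene"))
  all_blobs <- rbind(scene$colonies, scene$reflections)
  records <- lapply(seq_len(nrow(all_blobs)), function(i) {
    b <- all_blobs[i, ]
    list(id = b$id,
         bbox = c(b$row - b$radius, b$col - b$radius,
                  b$row + b$radius, b$col + b$radius),
         centroid = c(b$row, b$col),
         is_reflection = b$is_reflection)
  })
  doc <- list(image = image_name, count = scene$true_count,
              colonies = records)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a JSON annotation file
#'
#' @param path file written by [write_annotations()] (or any file in the
#'   same bounding-box/centroid JSON layout).
#' @return A list with `image`, `count`, and a data frame `colonies` with
#'   columns `id`, `rmin`, `cmin`, `rmax`, `cmax`, `row`, `col`,
#'   `is_reflection`.
#' @export
read_annotations <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  n <- length(doc$colonies)
  colonies <- data.frame(
    id = integer(n), rmin = numeric(n), cmin = numeric(n),
    rmax = numeric(n), cmax = numeric(n),
    row = numeric(n), col = numeric(n), is_reflection = logical(n))
  for (i in seq_len(n)) {
    r <- doc$colonies[[i]]
    colonies[i, ] <- list(r$id, r$bbox[[1]], r$bbox[[2]], r$bbox[[3]],
                          r$bbox[[4]], r$centroid[[1]], r$centroid[[2]],
                          isTRUE(r$is_reflection))
  }
  list(image = doc$image, count = doc$count, colonies = colonies)
}
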