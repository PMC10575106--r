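# End-to-end pipeline: synth -> train -> predict -> postprocess ->
# localize -> count -> eval, with file artifacts and a manifest.

#' Pipeline configuration
#'
#' @param out_dir output directory (created if missing).
#' @param n_scenes number of synthetic scenes for training.
#' @param n_test number of additional held-out test scenes (generated with
#'   `reflection_prob = 1` so the bezel correction is exercised).
#' @param generator a [generator_config()].
#' @param unet a [unet_config()].
#' @param train a [train_config()].
#' @param localize a [localize_params()].
#' @param mode counting mode for the counts table.
#' @param seed master seed; scene seeds and the training seed derive from
#'   it.
#' @param write_scenes write scene PNGs and annotation JSONs to disk.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir,
                            n_scenes = 30L, n_test = 10L,
                            generator = generator_config(height = 256L,
                                                         width = 256L),
                            unet = unet_config(input_size = 256L),
                            train = train_config(epochs = 5L),
                            localize = localize_params(),
                            mode = c("hybrid", "uniform", "naive"),
                            seed = 1L, write_scenes = FALSE) {
  structure(list(out_dir = out_dir, n_scenes = as.integer(n_scenes),
                 n_test = as.integer(n_test), generator = generator,
                 unet = unet, train = train, localize = localize,
                 mode = match.arg(mode), seed = as.integer(seed),
                 write_scenes = isTRUE(write_scenes)),
            class = "pipeline_config")
}

#' Run the full counting pipeline on synthetic scenes
#'
#' Generates scenes, trains the segmentation model, predicts and
#' post-processes masks for held-out reflective test scenes, localizes
#' each dish, counts under all three modes, and evaluates MAE/sMAPE.
#' Every stage leaves file artifacts under `config$out_dir`; a manifest
#' JSON records the stages completed, seeds and a configuration hash.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with `manifest`, `train_result`, `counts`
#'   (data frame), `metrics` ([stratified_report()]), and `ablation`
#'   ([ablation_table()]).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  done <- function(s) stages <<- c(stages, s)
  fail <- function(stage, e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)

  scenes <- tryCatch(
    lapply(seq_len(config$n_scenes),
           function(i) generate_scene(config$generator, config$seed + i)),
    error = function(e) fail("synth", e))
  test_gen <- config$generator
  test_gen$reflection_prob <- 1
  test_scenes <- tryCatch(
    lapply(seq_len(config$n_test),
           function(i) generate_scene(test_gen, config$seed + 10000L + i)),
    error = function(e) fail("synth", e))
  if (config$write_scenes) {
    sdir <- file.path(config$out_dir, "scenes")
    dir.create(sdir, showWarnings = FALSE)
    for (i in seq_along(scenes)) {
      write_image_png(scenes[[i]]$image,
                      file.path(sdir, sprintf("train_%03d.png", i)))
      write_annotations(scenes[[i]],
                        file.path(sdir, sprintf("train_%03d.json", i)),
                        sprintf("train_%03d.png", i))
    }
  }
  done("synth")

  ds <- tryCatch(make_training_set(scenes, config$unet),
                 error = function(e) fail("targets", e))
  done("targets")

  model <- build_model(config$unet, seed = config$seed)
  tr_cfg <- config$train
  tr_cfg$seed <- config$seed + 1L
  tr <- tryCatch(train_unet(model, ds, tr_cfg),
                 error = function(e) fail("train", e))
  utils::write.csv(tr$history,
                   file.path(config$out_dir, "training_history.csv"),
                   row.names = FALSE)
  done("train")

  masks <- locs <- vector("list", length(test_scenes))
  truths <- vapply(test_scenes, `[[`, numeric(1), "true_count")
  for (i in seq_along(test_scenes)) {
    pr <- tryCatch(
      predict_segmentation(tr$model, test_scenes[[i]]$image),
      error = function(e) fail("predict", e))
    masks[[i]] <- tryCatch(postprocess_mask(pr$mask),
                           error = function(e) fail("postprocess", e))
    locs[[i]] <- tryCatch(
      localize_dish(test_scenes[[i]]$image, config$localize),
      error = function(e) fail("localize", e))
  }
  done("predict"); done("postprocess"); done("localize")

  counts <- do.call(rbind, lapply(seq_along(masks), function(i) {
    r <- hybrid_count(masks[[i]], locs[[i]], config$mode)
    data.frame(image = i, true = truths[i], n = r$n, n_naive = r$n_naive,
               n_uniform = r$n_uniform, n_hybrid = r$n_hybrid,
               inner = ifelse(is.na(r$inner_count), NA, r$inner_count),
               bezel = ifelse(is.na(r$bezel_count), NA, r$bezel_count),
               used_fallback = r$used_fallback)
  }))
  utils::write.csv(counts, file.path(config$out_dir, "counts.csv"),
                   row.names = FALSE)
  done("count")

  metrics <- stratified_report(counts$true, counts$n)
  abl <- ablation_table(masks, locs, truths)
  utils::write.csv(abl, file.path(config$out_dir, "ablation.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(mae = metrics$all$mae, smape = metrics$all$smape,
         n_images = metrics$all$n_images,
         under_100 = list(mae = metrics$under$mae,
                          smape = metrics$under$smape,
                          n_images = metrics$under$n_images)),
    file.path(config$out_dir, "metrics.json"), auto_unbox = TRUE,
    digits = NA)
  done("eval")

  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL
  cfg_json <- jsonlite::toJSON(cfg_for_hash, auto_unbox = TRUE,
                               force = TRUE, digits = NA)
  manifest <- list(
    package = "cfuhybrid",
    version = as.character(utils::packageVersion("cfuhybrid")),
    seed = config$seed,
    mode = config$mode,
    stages = stages,
    config_hash = sprintf("%08x", sum(utf8ToInt(cfg_json) *
                                        seq_along(utf8ToInt(cfg_json))) %%
                            .Machine$integer.max),
    n_scenes = config$n_scenes, n_test = config$n_test)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, train_result = tr, counts = counts,
                 metrics = metrics, ablation = abl))
}
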