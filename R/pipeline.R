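# End-to-end slide pipeline and its configuration: foreground detection ->
# tessellation -> stain normalisation -> classification -> heatmaps ->
# lobule detection -> exports, with a manifest for reproducible reruns.

#' Pipeline configuration
#'
#' Defaults reproduce the reference protocol constants: 128/256-micron
#' patch targets for the 512/1024-px models, Adam at 1e-5, batch 16, 50
#' epochs, dropout 0.5, lobule area thresholds 400,000 px (40x) /
#' 250,000 px (20x), x32 enlargement, 250-micron peri-lobular width.
#'
#' @param mpp slide microns per pixel.
#' @param target_um tessellation patch edge in microns.
#' @param model_input_px model input side.
#' @param min_fg_fraction minimum per-cell tissue fraction.
#' @param seed pipeline seed.
#' @param train train_config overrides (list).
#' @param augment augment_config overrides (list).
#' @param lobules lobule_params overrides (list).
#' @param log_level "info" or "quiet".
#' @export
pipeline_config <- function(mpp = 0.25, target_um = 128, model_input_px = 512,
                            min_fg_fraction = 0.5, seed = 1,
                            train = list(), augment = list(), lobules = list(),
                            log_level = "info") {
  cfg <- list(
    mpp = mpp, target_um = target_um, model_input_px = model_input_px,
    min_fg_fraction = min_fg_fraction, seed = as.integer(seed),
    train = utils::modifyList(unclass(train_config()), train),
    augment = utils::modifyList(unclass(augment_config()), augment),
    lobules = utils::modifyList(unclass(lobule_params(mpp = mpp)), lobules),
    log_level = log_level)
  structure(cfg, class = "pipeline_config")
}

#' Save a pipeline configuration as YAML
#' @param cfg a pipeline_config.
#' @param path output YAML file.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Load a pipeline configuration from YAML
#' @param path YAML file written by \code{save_config}.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  structure(raw, class = "pipeline_config")
}

log_stage <- function(cfg, fmt, ...) {
  if (!identical(cfg$log_level, "quiet"))
    message(sprintf("[nbt %s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)))
}

run_stage <- function(cfg, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  log_stage(cfg, "%-12s %.2fs", name, proc.time()[["elapsed"]] - t0)
  out
}

#' Run the whole-slide pre-processing pipeline
#'
#' Executes foreground detection, physical-size tessellation, Reinhard
#' normalisation, patch classification, heatmap rendering, lobule
#' detection, and writes all artifacts plus a manifest (inputs, config,
#' seed, content hashes) into `out_dir`. Deterministic stages rerun
#' byte-identically under the same manifest.
#'
#' @param slide a synthetic_slide, an H x W x 3 array, or a PNG path.
#' @param model a trained nbt_model or a path readable by
#'   \code{load_model}.
#' @param out_dir output directory (created if needed).
#' @param cfg a pipeline_config.
#' @param reference stain_stats reference (default the packaged synthetic
#'   reference).
#' @return invisibly, a list with the class map, lobule detection, and
#'   output file paths.
#' @export
run_pipeline <- function(slide, model, out_dir, cfg = pipeline_config(),
                         reference = default_stain_reference()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(slide)) slide <- read_image_png(slide)
  if (is.character(model)) model <- load_model(model)
  mpp <- if (inherits(slide, "synthetic_slide")) slide$mpp else cfg$mpp
  img <- if (inherits(slide, "synthetic_slide")) slide$image else slide

  fg <- run_stage(cfg, "foreground",
    detect_foreground(img, mpp = mpp))
  grid <- run_stage(cfg, "tessellate", {
    spec <- tessellation_spec(cfg$target_um, mpp, cfg$model_input_px)
    tessellate(img, fg, spec, cfg$min_fg_fraction)
  })
  map <- run_stage(cfg, "classify",
    classify_slide(model, grid, normalizer = reference))
  lp <- do.call(lobule_params, utils::modifyList(list(mpp = mpp),
          cfg$lobules[setdiff(names(cfg$lobules), character(0))]))
  lob <- run_stage(cfg, "lobules", detect_lobules(map, lp))

  paths <- list(
    class_map = file.path(out_dir, "class_map.csv"),
    heatmap = file.path(out_dir, "probability_heatmap.png"),
    class_geojson = file.path(out_dir, "class_map.geojson"),
    lobule_geojson = file.path(out_dir, "lobules.geojson"),
    lobule_table = file.path(out_dir, "lobule_table.csv"),
    manifest = file.path(out_dir, "manifest.json"))
  run_stage(cfg, "export", {
    write_class_map_csv(map, paths$class_map)
    hm <- probability_heatmap(map, upscale = 8, smooth = TRUE)
    write_image_png(hm, paths$heatmap)
    write_qupath_geojson(map, paths$class_geojson)
    write_qupath_geojson(lob, paths$lobule_geojson)
    write_lobule_table(lob, paths$lobule_table)
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("nbtclassify")),
    seed = cfg$seed,
    mpp = mpp,
    config = unclass(cfg),
    n_lobules_detected = length(lob$components),
    outputs = lapply(paths[setdiff(names(paths), "manifest")], function(p)
      list(path = basename(p), md5 = file_md5(p))))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
  log_stage(cfg, "done: %d lobules, %d/%d foreground cells",
            length(lob$components), nrow(grid$index), grid$rows * grid$cols)
  invisible(list(class_map = map, lobules = lob, foreground = fg,
                 grid = grid, paths = paths))
}
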