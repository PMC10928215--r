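#' Pipeline configuration
#'
#' All scalar constants of the mapping pipeline with their defaults: the
#' mosaic calibration factor (-83 dB), the 150 m speckle-filter radius, the
#' minimum C-band observation count (2), the canopy-cover threshold (10%,
#' strict), the footprint slope limits (12/15 deg) and the conditional AGB
#' threshold (40 Mg ha^-1), the 25 m height cap, the aggregation cell size
#' and minimum footprint count (2), the 10 deg stratum split, the 60/40
#' train/validation split, the prune count (10), the 10 Mg ha^-1 bias-
#' correction bin, the 0.47 carbon fraction, and the site-filter thresholds
#' (100 m buffer; NDVI < 0.15; SAR < 2 dB; heterogeneity ratio <= 0.25).
#'
#' @param ... overrides of any default, by name.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    cf_db = -83.0,
    focal_radius_m = 150,
    min_cband_obs = 2,
    cover_threshold_pct = 10,
    target_year = 2007,
    slope_band_deg = 12,
    slope_max_deg = 15,
    low_agb_threshold = 40,
    height_cap_m = 25,
    cell_size_m = 400,
    min_footprints = 2,
    footprints_per_cell = 4.14,
    stratum_slope_deg = 10,
    train_frac = 0.6,
    prune_k = 10,
    n_trees = 500,
    bin_width = 10,
    carbon_fraction = 0.47,
    buffer_m = 100,
    ndvi_stability = 0.15,
    sar_stability_db = 2,
    heterogeneity_max = 0.25,
    n_field_plots_north = 26,
    n_field_plots_south = 14,
    field_plot_scatter = 0.2,
    n_validation_sites = 20,
    agb_from = "footprint",
    r2_method = "pearson")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    rlang::abort(paste("unknown config field(s):",
                       paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline config as YAML
#' @param config a `pipeline_config`.
#' @param path file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Build the co-registered covariate stack from a scene
#'
#' Applies the sensor-specific preprocessing: L-band DN is speckle-filtered
#' in the linear power domain (circular focal mean) then calibrated to
#' gamma-naught, with the HV-HH ratio band; pooled C-band temporal mean,
#' standard deviation and minimum with the under-observed gap mask; cloud-
#' masked optical temporal means and NDVI max/min/range; elevation and Horn
#' slope; and latitude/longitude coordinate bands.
#'
#' @param scene a `synthetic_scene`.
#' @param config a [pipeline_config()].
#' @return list with `stack` (named list of `grid_raster` bands), `gap`
#'   (logical C-band gap raster) and `forest` (logical mask for the target
#'   year).
#' @export
build_covariate_stack <- function(scene, config = pipeline_config()) {
  smooth_cal <- function(dn) {
    lin <- gr_like(dn, db_to_linear(unclass(dn_to_gamma0(dn, config$cf_db))))
    gr_like(dn, linear_to_db(unclass(focal_mean(lin, config$focal_radius_m))))
  }
  g_hh <- smooth_cal(scene$hh_dn)
  g_hv <- smooth_cal(scene$hv_dn)
  cb <- envisat_stats(scene$cband_hh, scene$cband_vv,
                      min_obs = config$min_cband_obs)
  opt <- landsat_composite(scene$optical, scene$optical_qa)
  stack <- c(list(gamma0_hh = g_hh, gamma0_hv = g_hv,
                  sar_ratio = sar_ratio(g_hv, g_hh),
                  cband_mean = cb$mean, cband_std = cb$std,
                  cband_min = cb$min),
             opt,
             list(elevation = scene$dem,
                  slope = slope_from_dem(scene$dem),
                  latitude = gr_y(scene$dem),
                  longitude = gr_x(scene$dem)))
  forest <- build_forest_mask(scene$cover2000, scene$lossyear,
                              target_year = config$target_year,
                              threshold = config$cover_threshold_pct)
  list(stack = stack, gap = cb$gap, forest = forest)
}

cband_features <- c("cband_mean", "cband_std", "cband_min")

assign_cell_stratum <- function(cells, strata, cell_size_m) {
  labs <- names(strata)
  vals <- sapply(labs, function(nm) {
    cell_band_means(list(s = gr_like(strata[[nm]],
                                     unclass(strata[[nm]]) * 1)),
                    cells$cell_x, cells$cell_y, cell_size_m)$s
  })
  vals[is.na(vals)] <- 0
  labs[max.col(vals, ties.method = "first")]
}

#' Run the full mapping pipeline on a synthetic scene
#'
#' Executes the stages in order: simulate the scene; preprocess the
#' covariate stack; fit the regional allometries from synthetic field
#' plots; sample, convert, filter and aggregate LiDAR footprints;
#' train/validation split; stratified random-forest training with
#' node-purity pruning; wall-to-wall prediction and stitching; cell-level
#' evaluation; binned zero-intercept bias correction; map summaries; and
#' site-based validation. Any prefix of the stage list can be requested.
#'
#' @param config a [pipeline_config()].
#' @param scene_cfg a [scene_config()]; its seed is the scene seed.
#' @param seed integer seed driving footprint sampling, splits and forest
#'   growth.
#' @param stages stage names to run (a prefix of the default order).
#' @param outdir optional directory: artifacts and a JSON manifest are
#'   written there.
#' @return list of stage artifacts: `scene`, `stack`, `models`
#'   (allometries), `footprints`, `cells`, `strata`, `rf_models`,
#'   `map_raw`, `evaluation`, `corrector`, `map` (bias-corrected),
#'   `evaluation_corrected`, `summary`, `histogram`, `site_filter`,
#'   `site_accuracy`, `manifest`.
#' @export
run_agb_pipeline <- function(config = pipeline_config(),
                             scene_cfg = scene_config(), seed = 1L,
                             stages = c("simulate", "preprocess",
                                        "footprints", "train", "predict",
                                        "correct", "validate", "compare"),
                             outdir = NULL) {
  all_stages <- c("simulate", "preprocess", "footprints", "train",
                  "predict", "correct", "validate", "compare")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if (!identical(stages, all_stages[seq_along(stages)])) {
    rlang::abort("`stages` must be a prefix of the canonical stage order")
  }
  res <- list()
  seed <- as.integer(seed)

  # simulate
  scene_cfg$seed <- seed
  res$scene <- generate_scene(scene_cfg)
  if (!"preprocess" %in% stages) return(res)

  cov <- build_covariate_stack(res$scene, config)
  res$stack <- cov$stack; res$gap <- cov$gap; res$forest <- cov$forest
  if (!"footprints" %in% stages) return(res)

  # regional allometries refitted from synthetic field plots
  plots_n <- generate_field_plots("north", config$n_field_plots_north,
                                  allometry_north(),
                                  scatter = config$field_plot_scatter,
                                  seed = seed + 11L)
  plots_s <- generate_field_plots("south", config$n_field_plots_south,
                                  allometry_south(),
                                  scatter = config$field_plot_scatter,
                                  seed = seed + 12L)
  res$field_plots <- dplyr::bind_rows(plots_n, plots_s)
  res$models <- list(north = fit_power_allometry(plots_n, "north"),
                     south = fit_power_allometry(plots_s, "south"))

  n_cells_grid <- ceiling(scene_cfg$nrow * scene_cfg$pixel_size /
                            config$cell_size_m) *
    ceiling(scene_cfg$ncol * scene_cfg$pixel_size / config$cell_size_m)
  n_fp <- round(config$footprints_per_cell * n_cells_grid)
  fp <- sample_footprints(res$scene, n_fp, seed = seed + 1L)
  fp <- convert_heights(fp, res$models, cap_m = config$height_cap_m)
  fp <- filter_footprints(fp, slope_max = config$slope_max_deg,
                          slope_band = config$slope_band_deg,
                          agb_max = config$low_agb_threshold)
  res$footprints <- fp
  cells <- aggregate_to_cells(fp, config$cell_size_m, stack = res$stack,
                              forest = res$forest,
                              min_count = config$min_footprints,
                              agb_from = config$agb_from,
                              models = res$models)
  cells <- split_cells(cells, train_frac = config$train_frac,
                       seed = seed + 2L)
  res$cells <- cells
  if (!"train" %in% stages) return(res)

  res$strata <- stratify(res$stack$slope, res$gap, res$forest,
                         slope_split = config$stratum_slope_deg)
  cells$stratum <- assign_cell_stratum(cells, res$strata, config$cell_size_m)
  res$cells <- cells
  all_features <- names(res$stack)
  res$rf_models <- list()
  for (nm in names(res$strata)) {
    feats <- if (nm == "no_cband") {
      setdiff(all_features, cband_features)
    } else all_features
    sub <- cells[cells$stratum == nm, ]
    m <- train_region_model(sub, feats, region = nm, seed = seed + 3L,
                            n_trees = config$n_trees)
    res$rf_models[[nm]] <- prune_and_retrain(m, sub, k = config$prune_k)
  }
  if (!"predict" %in% stages) return(res)

  maps <- purrr::imap(res$rf_models, function(m, nm)
    predict_map(m, res$stack, res$strata[[nm]]))
  res$map_raw <- stitch_strata(maps, res$strata, res$forest)
  res$evaluation <- evaluate_cells(res$map_raw, cells, config$cell_size_m,
                                   subset = "validation",
                                   r2_method = config$r2_method)
  if (!"correct" %in% stages) return(res)

  val <- cells[cells$split == "validation", ]
  pred_cells <- cell_band_means(list(p = res$map_raw), val$cell_x,
                                val$cell_y, config$cell_size_m)$p
  res$corrector <- fit_bias_corrector(pred_cells, val$agb,
                                      bin_width = config$bin_width)
  res$map <- apply_bias_correction(res$corrector, res$map_raw)
  res$evaluation_corrected <- evaluate_cells(res$map, cells,
                                             config$cell_size_m,
                                             subset = "validation",
                                             r2_method = config$r2_method)
  if (!"validate" %in% stages) return(res)

  sv <- generate_validation_sites(res$scene, config$n_validation_sites,
                                  fraction_unstable = 0.2,
                                  fraction_heterogeneous = 0.2,
                                  seed = seed + 4L,
                                  buffer_m = config$buffer_m)
  res$site_filter <- filter_sites(sv$sites, res$forest, sv$ndvi_annual,
                                  sv$hh_annual, sv$hv_annual, sv$agb,
                                  buffer_m = config$buffer_m,
                                  ndvi_limit = config$ndvi_stability,
                                  sar_limit = config$sar_stability_db,
                                  het_limit = config$heterogeneity_max)
  if (nrow(res$site_filter$sites) >= 2) {
    res$site_accuracy <- site_metrics(res$map, res$site_filter$sites,
                                      aggregation = "pixel")
  }
  if (!"compare" %in% stages) return(res)

  res$summary <- agb_to_carbon(res$map,
                               carbon_fraction = config$carbon_fraction)
  res$histogram <- histogram_10(res$map, bin_width = config$bin_width)
  res$comparison <- buffered_boxplot_stats(
    list(corrected = res$map, raw = res$map_raw, truth = mask_to_forest(
      res$scene$true_agb, res$forest)),
    res$site_filter$sites %||na% sv$sites)

  res$manifest <- list(
    config = unclass(config),
    scene_seed = scene_cfg$seed, seed = seed,
    config_hash = rlang::hash(unclass(config)),
    n_cells = nrow(cells),
    stages = stages)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_stack(list(agb_corrected = res$map, agb_raw = res$map_raw), outdir)
    utils::write.csv(res$cells[, setdiff(names(res$cells), "trees")],
                     file.path(outdir, "cells.csv"), row.names = FALSE)
    jsonlite::write_json(res$manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

`%||na%` <- function(a, b) if (nrow(a) > 0) a else b

mask_to_forest <- function(r, forest) {
  m <- unclass(r)
  m[!unclass(forest)] <- NA_real_
  gr_like(r, m)
}
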