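#' Scene configuration for the synthetic-data generator
#'
#' Defines the study conditions emulated by [generate_scene()]: grid and
#' pixel size, the range and spatial correlation of the latent AGB surface,
#' terrain relief, the saturating sensor-response parameters for each
#' covariate family (`y = c0 + c1 * (1 - exp(-AGB / k)) + noise`), the
#' Lorey's-height observation noise, cloud contamination and the C-band
#' coverage gap.
#'
#' @param nrow,ncol grid size in pixels.
#' @param pixel_size pixel edge (m), default 50.
#' @param origin planar x/y of the lower-left corner (m).
#' @param agb_range latent AGB range (Mg ha^-1), default 0-250.
#' @param corr_length correlation length of the latent AGB field (pixels):
#'   the standard deviation of the Gaussian smoothing kernel.
#' @param dem_relief total relief of the synthetic terrain (m).
#' @param dem_corr_length correlation length of the terrain (pixels).
#' @param height_noise_sd sd of the Lorey's-height observation noise (m),
#'   default 5.9 (the height-retrieval RMSE the pipeline assumes).
#' @param cloud_fraction per-observation probability an optical observation
#'   is cloudy, in `[0, 1]`.
#' @param gap_fraction fraction of the scene with under-observed C-band
#'   coverage (fewer than 2 observations).
#' @param loss_fraction fraction of pixels flagged with a 2001-2012 forest
#'   loss year.
#' @param speckle_sd sd of the multiplicative (log-scale) speckle noise on
#'   the L-band linear power.
#' @param cband_noise_sd additive dB noise per C-band observation.
#' @param optical_noise_sd additive reflectance noise per optical
#'   observation.
#' @param n_cband,n_optical number of time-stack slices per sensor.
#' @param sensor list of saturating-response parameters `c(c0, c1, k)` per
#'   band; see defaults.
#' @param seed integer seed; the same config and seed give bit-identical
#'   scenes.
#' @return A `scene_config` list.
#' @export
scene_config <- function(nrow = 200, ncol = 200, pixel_size = 50,
                         origin = c(0, 0), agb_range = c(0, 250),
                         corr_length = 10, dem_relief = 800,
                         dem_corr_length = 20, height_noise_sd = 5.9,
                         cloud_fraction = 0.2, gap_fraction = 0.10,
                         loss_fraction = 0.03, speckle_sd = 0.15,
                         cband_noise_sd = 0.8, optical_noise_sd = 0.01,
                         n_cband = 8, n_optical = 6,
                         sensor = NULL, seed = 1L) {
  if (!is.numeric(nrow) || !is.numeric(ncol) || nrow < 1 || ncol < 1) {
    rlang::abort("grid dimensions must be positive")
  }
  if (any(agb_range < 0) || diff(agb_range) <= 0) {
    rlang::abort("`agb_range` must be nonnegative with max > min")
  }
  stopifnot(height_noise_sd >= 0, cloud_fraction >= 0, cloud_fraction <= 1,
            gap_fraction >= 0, gap_fraction <= 1)
  default_sensor <- list(
    # dB-domain responses for SAR, reflectance for optical
    hv      = c(c0 = -22, c1 = 12, k = 80),
    hh      = c(c0 = -12, c1 = 6,  k = 50),
    cband   = c(c0 = -13, c1 = 4,  k = 40),
    nir     = c(c0 = 0.18, c1 = 0.30, k = 50),
    red     = c(c0 = 0.26, c1 = -0.20, k = 50),
    green   = c(c0 = 0.14, c1 = -0.08, k = 60),
    swir1   = c(c0 = 0.30, c1 = -0.22, k = 45))
  if (!is.null(sensor)) default_sensor[names(sensor)] <- sensor
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 pixel_size = pixel_size, origin = origin,
                 agb_range = agb_range, corr_length = corr_length,
                 dem_relief = dem_relief, dem_corr_length = dem_corr_length,
                 height_noise_sd = height_noise_sd,
                 cloud_fraction = cloud_fraction,
                 gap_fraction = gap_fraction, loss_fraction = loss_fraction,
                 speckle_sd = speckle_sd, cband_noise_sd = cband_noise_sd,
                 optical_noise_sd = optical_noise_sd,
                 n_cband = as.integer(n_cband),
                 n_optical = as.integer(n_optical),
                 sensor = default_sensor, seed = as.integer(seed)),
            class = "scene_config")
}

# run code with a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# stationary Gaussian random field: white noise circularly convolved with a
# Gaussian kernel of sd `corr_length` pixels (FFT), then standardized
gaussian_field <- function(nr, nc, corr_length) {
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (corr_length <= 0) return(w)
  dr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  kern <- exp(-0.5 * outer(dr^2, dc^2, "+") / corr_length^2)
  f <- Re(stats::fft(stats::fft(w) * stats::fft(kern), inverse = TRUE)) /
    (nr * nc)
  (f - mean(f)) / stats::sd(f)
}

rescale_range <- function(m, lo, hi) {
  lo + (m - min(m)) / (max(m) - min(m)) * (hi - lo)
}

# probability-integral rescale: maps the standardized Gaussian field onto the
# configured range with an approximately uniform marginal, so the landscape
# spans low- and high-biomass forest rather than clustering mid-range
rescale_uniform <- function(m, lo, hi) {
  lo + stats::pnorm(m) * (hi - lo)
}

sat_response <- function(agb, p) p[["c0"]] + p[["c1"]] * (1 - exp(-agb / p[["k"]]))

#' Generate a synthetic scene
#'
#' Builds a complete multi-sensor scene around a latent AGB surface: a
#' smoothed Gaussian random field rescaled to the configured range; L-band
#' HH/HV digital-number mosaics derived from AGB through a saturating
#' response with multiplicative speckle; a weakly AGB-dependent C-band time
#' stack with per-pixel observation counts (an under-observed blob creates
#' the no-C-band region); an optical time stack whose NDVI saturates in AGB,
#' with cloud-flagged observations; a smooth DEM providing both flat
#' (<= 10 deg) and rugged terrain; canopy-cover and loss-year layers; and a
#' north/south region-label raster split at the scene's mid-latitude.
#'
#' @param config a [scene_config()].
#' @return A `synthetic_scene` list of `grid_raster` layers and time stacks
#'   (see fields in the source), carrying its config.
#' @export
generate_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  cfg <- config
  with_seed(cfg$seed, {
    tmpl <- grid_raster(matrix(0, cfg$nrow, cfg$ncol), cfg$origin,
                        cfg$pixel_size)
    agb <- rescale_uniform(gaussian_field(cfg$nrow, cfg$ncol, cfg$corr_length),
                           cfg$agb_range[1], cfg$agb_range[2])
    true_agb <- gr_like(tmpl, agb)

    dem <- gr_like(tmpl, rescale_range(
      gaussian_field(cfg$nrow, cfg$ncol, cfg$dem_corr_length),
      0, cfg$dem_relief))
    slope <- slope_from_dem(dem)

    # canopy cover saturates quickly in AGB; sparse pixels become non-forest
    cover <- gr_like(tmpl, pmin(100, 100 * (1 - exp(-agb / 15))))
    loss <- matrix(0, cfg$nrow, cfg$ncol)
    n_loss <- round(cfg$loss_fraction * length(loss))
    if (n_loss > 0) {
      loss[sample.int(length(loss), n_loss)] <-
        sample(2001:2012, n_loss, replace = TRUE)
    }
    lossyear <- gr_like(tmpl, loss)

    # L-band mosaics: saturating dB response -> linear power -> speckle -> DN
    mk_dn <- function(p) {
      g0 <- sat_response(agb, p)
      lin <- db_to_linear(g0) *
        exp(stats::rnorm(length(agb), 0, cfg$speckle_sd))
      gr_like(tmpl, gamma0_to_dn(linear_to_db(lin)))
    }
    hv_dn <- mk_dn(cfg$sensor$hv)
    hh_dn <- mk_dn(cfg$sensor$hh)

    # C-band: observation counts low inside a smooth "gap" blob
    gap_field <- gaussian_field(cfg$nrow, cfg$ncol, cfg$dem_corr_length)
    gap <- gap_field < stats::quantile(gap_field, cfg$gap_fraction)
    n_obs <- matrix(pmin(cfg$n_cband, 2 + stats::rpois(length(agb), 3)),
                    cfg$nrow, cfg$ncol)
    n_obs[gap] <- stats::rbinom(sum(gap), 1, 0.5)
    cband_resp <- sat_response(agb, cfg$sensor$cband)
    mk_cslice <- function(i) {
      v <- cband_resp + stats::rnorm(length(agb), 0, cfg$cband_noise_sd)
      v[n_obs < i] <- NA_real_
      gr_like(tmpl, v)
    }
    # alternate slices between the HH and VV stacks so pooled counts match
    cband_hh <- lapply(seq(1, cfg$n_cband, by = 2), mk_cslice)
    cband_vv <- lapply(seq(2, cfg$n_cband, by = 2), mk_cslice)

    # optical stack with per-observation cloud flags
    optical <- list(); qa <- list()
    for (i in seq_len(cfg$n_optical)) {
      qa[[i]] <- gr_like(tmpl, matrix(
        stats::rbinom(length(agb), 1, cfg$cloud_fraction),
        cfg$nrow, cfg$ncol))
    }
    for (bn in c("green", "red", "nir", "swir1")) {
      optical[[bn]] <- lapply(seq_len(cfg$n_optical), function(i) {
        gr_like(tmpl, pmax(0.001, sat_response(agb, cfg$sensor[[bn]]) +
          stats::rnorm(length(agb), 0, cfg$optical_noise_sd)))
      })
    }

    region <- gr_like(tmpl, matrix(
      rep(c(1, 2), c(ceiling(cfg$nrow / 2), floor(cfg$nrow / 2))),
      cfg$nrow, cfg$ncol))

    structure(list(config = cfg, true_agb = true_agb, dem = dem,
                   slope = slope, cover2000 = cover, lossyear = lossyear,
                   forest = build_forest_mask(cover, lossyear),
                   hh_dn = hh_dn, hv_dn = hv_dn,
                   cband_hh = cband_hh, cband_vv = cband_vv,
                   cband_n_obs = gr_like(tmpl, n_obs),
                   optical = optical, optical_qa = qa,
                   region = region),
              class = "synthetic_scene")
  })
}

region_label <- function(code) c("north", "south")[code]

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d px (%g m), AGB %g-%g Mg/ha, seed %d\n",
              x$config$nrow, x$config$ncol, x$config$pixel_size,
              x$config$agb_range[1], x$config$agb_range[2], x$config$seed))
  cat(sprintf("  forest pixels: %d (%.0f%%)\n", sum(x$forest),
              100 * mean(x$forest)))
  invisible(x)
}

#' Sample LiDAR footprints over a scene
#'
#' Draws footprint locations uniformly over forest pixels (with jitter
#' inside the pixel). The true Lorey's height is obtained by inverting the
#' region's generating allometry at the pixel's true AGB; the observed
#' height adds Gaussian noise (sd from the scene config) floored at 0 m.
#'
#' @param scene a `synthetic_scene`.
#' @param n number of footprints (> 0).
#' @param seed integer seed.
#' @param models named list of generating `allometric_model`s per region
#'   (default the published north/south models).
#' @return tibble with `id`, `x`, `y`, `lorey` (observed, m), `lorey_true`,
#'   `slope` (deg), `region`, `agb_true` (Mg ha^-1).
#' @export
sample_footprints <- function(scene, n, seed = 1L,
                              models = list(north = allometry_north(),
                                            south = allometry_south())) {
  stopifnot(inherits(scene, "synthetic_scene"), n > 0)
  idx <- which(unclass(scene$forest))
  if (length(idx) == 0) rlang::abort("scene has no forest pixels")
  with_seed(seed, {
    pick <- sample(idx, n, replace = TRUE)
    nr <- nrow(scene$true_agb)
    row <- (pick - 1L) %% nr + 1L
    col <- (pick - 1L) %/% nr + 1L
    px <- gr_pixel_size(scene$true_agb); o <- gr_origin(scene$true_agb)
    x <- o[1] + (col - 1L) * px + stats::runif(n, 0, px)
    y <- o[2] + (nr - row) * px + stats::runif(n, 0, px)
    agb <- scene$true_agb[cbind(row, col)]
    reg <- region_label(scene$region[cbind(row, col)])
    lt <- vapply(seq_len(n), function(i)
      lorey_from_agb(models[[reg[i]]], agb[i]), numeric(1))
    lobs <- pmax(0, lt + stats::rnorm(n, 0, scene$config$height_noise_sd))
    tibble::tibble(id = seq_len(n), x = x, y = y, lorey = lobs,
                   lorey_true = lt,
                   slope = scene$slope[cbind(row, col)],
                   region = reg, agb_true = agb)
  })
}
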