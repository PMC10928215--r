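#' Generate synthetic field plots for allometry fitting
#'
#' Each plot is built so that its tree-level biomass (per the tree
#' allometry) and its Lorey's height jointly satisfy the target power law
#' `AGB = a * Lorey^b` up to a configurable multiplicative scatter: all
#' trees in a plot share the target height (so Lorey's height equals it
#' exactly) and the diameters are scaled so the summed tree biomass matches
#' the target density exactly. All DBH respect the 5 cm census threshold.
#'
#' @param region region label attached to every plot.
#' @param n_plots number of plots (>= 2).
#' @param model generating `allometric_model`.
#' @param scatter relative (log-scale) sd of the multiplicative deviation of
#'   plot AGB from the power law; 0 gives exactly identifiable plots.
#' @param seed integer seed.
#' @param area_ha plot area (default 0.05 ha, a 12.5 m-radius circle).
#' @param lorey_range range of target Lorey's heights (m).
#' @return tibble with `plot_id`, `region`, `area_ha`, `lorey`, `agb`
#'   (realized values) and a `trees` list-column of tibbles (`dbh`, `height`).
#' @export
generate_field_plots <- function(region, n_plots, model = allometry_north(),
                                 scatter = 0.2, seed = 1L, area_ha = 0.05,
                                 lorey_range = c(6, 24)) {
  if (n_plots < 2) rlang::abort("`n_plots` must be at least 2")
  if (scatter < 0) rlang::abort("`scatter` must be nonnegative")
  with_seed(seed, {
    lorey <- stats::runif(n_plots, lorey_range[1], lorey_range[2])
    target <- predict_agb_from_lorey(model, lorey) *
      exp(stats::rnorm(n_plots, 0, scatter))
    plots <- purrr::map(seq_len(n_plots), function(j) {
      total_kg <- target[j] * 1000 * area_ha
      h <- lorey[j]
      # typical tree at 15 cm DBH sets the initial stem count
      n_tree <- max(1L, round(total_kg / tree_agb(15, h)))
      repeat {
        mult <- stats::runif(n_tree, 1, 2.5)
        # solve the common DBH scale so summed tree AGB hits the target
        s <- (total_kg / (0.1355 * h^0.817 * sum(mult^1.634)))^(1 / 1.634)
        if (s * min(mult) >= 5 || n_tree == 1L) break
        n_tree <- max(1L, floor(n_tree / 2))
      }
      dbh <- pmax(5, s * mult)
      tibble::tibble(dbh = dbh, height = rep(h, n_tree))
    })
    realized_lorey <- purrr::map_dbl(plots, loreys_height)
    realized_agb <- purrr::map_dbl(plots, plot_agb_density,
                                   area_ha = area_ha)
    tibble::tibble(
      plot_id = sprintf("%s_%03d", region, seq_len(n_plots)),
      region = region, area_ha = area_ha,
      lorey = realized_lorey, agb = realized_agb, trees = plots)
  })
}

buffer_index <- function(r, x, y, radius_m) {
  px <- gr_pixel_size(r)
  rc <- gr_locate(r, x, y)
  if (is.na(rc$row)) return(matrix(integer(0), 0, 2))
  k <- ceiling(radius_m / px)
  offs <- expand.grid(dr = -k:k, dc = -k:k)
  rows <- rc$row + offs$dr; cols <- rc$col + offs$dc
  ok <- rows >= 1 & rows <= nrow(r) & cols >= 1 & cols <= ncol(r)
  rows <- rows[ok]; cols <- cols[ok]
  o <- gr_origin(r)
  pcx <- o[1] + (cols - 0.5) * px
  pcy <- o[2] + (nrow(r) - rows + 0.5) * px
  keep <- (pcx - x)^2 + (pcy - y)^2 <= radius_m^2
  cbind(rows[keep], cols[keep])
}

#' Generate validation sites with known filter outcomes
#'
#' Places sites on fully forested neighbourhoods of the scene and
#' constructs, alongside the site table, the annual NDVI and SAR series and
#' an AGB surface such that the pass/fail status of every site against the
#' site-filter criteria (forest fraction, NDVI stability, SAR stability,
#' buffer heterogeneity) is known by construction. A configurable fraction
#' of sites is made to fail the temporal-stability criterion (NDVI or SAR
#' according to `unstable_mode`) and another fraction to fail the
#' heterogeneity criterion.
#'
#' @param scene a `synthetic_scene`.
#' @param n number of sites.
#' @param fraction_unstable,fraction_heterogeneous fractions in `[0, 1]`.
#' @param seed integer seed.
#' @param unstable_mode which stability criterion the unstable sites break:
#'   "ndvi" (default) or "sar".
#' @param buffer_m buffer radius (default 100 m).
#' @param years calendar years of the annual series.
#' @return list with `sites` (tibble incl. `expect_*` truth columns),
#'   `ndvi_annual`, `hh_annual`, `hv_annual` (lists of `grid_raster` per
#'   year), and `agb` (the AGB surface the heterogeneity filter reads).
#' @export
generate_validation_sites <- function(scene, n, fraction_unstable = 0,
                                      fraction_heterogeneous = 0, seed = 1L,
                                      unstable_mode = c("ndvi", "sar"),
                                      buffer_m = 100, years = 2007:2016) {
  unstable_mode <- match.arg(unstable_mode)
  stopifnot(fraction_unstable >= 0, fraction_unstable <= 1,
            fraction_heterogeneous >= 0, fraction_heterogeneous <= 1)
  tmpl <- scene$true_agb
  px <- gr_pixel_size(tmpl)
  with_seed(seed, {
    # candidate pixels: buffer entirely forest, and buffers well separated
    fm <- unclass(scene$forest)
    k <- ceiling(buffer_m / px) + 1L
    interior <- matrix(FALSE, nrow(fm), ncol(fm))
    interior[(k + 1):(nrow(fm) - k), (k + 1):(ncol(fm) - k)] <- TRUE
    cand <- which(fm & interior)
    cand <- cand[sample.int(length(cand))]
    nr <- nrow(fm)
    sel <- integer(0)
    for (p in cand) {
      r0 <- (p - 1L) %% nr + 1L; c0 <- (p - 1L) %/% nr + 1L
      ok <- TRUE
      for (q in sel) {
        if (max(abs(r0 - ((q - 1L) %% nr + 1L)),
                abs(c0 - ((q - 1L) %/% nr + 1L))) < 2L * k + 2L) {
          # require full-buffer forest and non-overlapping buffers
          ok <- FALSE; break
        }
      }
      buf <- buffer_index(tmpl, gr_x(tmpl)[r0, c0], gr_y(tmpl)[r0, c0],
                          buffer_m)
      if (ok && all(fm[buf])) sel <- c(sel, p)
      if (length(sel) == n) break
    }
    if (length(sel) < n) {
      rlang::abort("could not place the requested number of separated sites")
    }
    row <- (sel - 1L) %% nr + 1L; col <- (sel - 1L) %/% nr + 1L
    x <- gr_x(tmpl)[cbind(row, col)]; y <- gr_y(tmpl)[cbind(row, col)]
    site_agb <- unclass(scene$true_agb)[cbind(row, col)]
    site_agb <- pmax(site_agb, 10)  # keep the heterogeneity ratio defined

    n_u <- round(n * fraction_unstable)
    n_h <- round(n * fraction_heterogeneous)
    unstable <- seq_len(n) <= n_u
    hetero <- seq_len(n) > n_u & seq_len(n) <= n_u + n_h

    # stable annual backdrops; instability injected over whole buffers
    mk_series <- function(base) {
      lapply(seq_along(years), function(i) gr_like(tmpl, base))
    }
    ndvi_annual <- mk_series(0.8)
    hh_annual <- mk_series(-7)
    hv_annual <- mk_series(-12)
    agb_map <- unclass(scene$true_agb)
    for (i in seq_len(n)) {
      buf <- buffer_index(tmpl, x[i], y[i], buffer_m)
      if (unstable[i]) {
        if (unstable_mode == "ndvi") {
          m <- unclass(ndvi_annual[[3]]); m[buf] <- 0.8 - 0.3
          ndvi_annual[[3]] <- gr_like(tmpl, m)
        } else {
          m <- unclass(hh_annual[[3]]); m[buf] <- -7 - 3
          hh_annual[[3]] <- gr_like(tmpl, m)
        }
      }
      if (hetero[i]) {
        alt <- rep_len(c(1.8, 0.2), nrow(buf))
        agb_map[buf] <- site_agb[i] * alt
      } else {
        agb_map[buf] <- site_agb[i]
      }
    }
    sites <- tibble::tibble(
      id = sprintf("site_%03d", seq_len(n)), x = x, y = y,
      agb = site_agb, year = 2012L,
      expect_forest = TRUE,
      expect_ndvi = !(unstable & unstable_mode == "ndvi"),
      expect_sar = !(unstable & unstable_mode == "sar"),
      expect_homog = !hetero,
      expect_pass = !unstable & !hetero)
    list(sites = sites, ndvi_annual = ndvi_annual, hh_annual = hh_annual,
         hv_annual = hv_annual, agb = gr_like(tmpl, agb_map))
  })
}

#' Write a synthetic scene to disk
#'
#' Single-band layers go to TIFF via [write_stack()]; time stacks are
#' written slice by slice; a `scene_manifest.json` records the config and
#' seed.
#'
#' @param scene a `synthetic_scene`.
#' @param path output directory.
#' @return the path, invisibly.
#' @export
write_scene <- function(scene, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  bands <- list(true_agb = scene$true_agb, dem = scene$dem,
                slope = scene$slope, cover2000 = scene$cover2000,
                lossyear = scene$lossyear,
                forest = gr_like(scene$forest, unclass(scene$forest) * 1),
                hh_dn = scene$hh_dn, hv_dn = scene$hv_dn,
                cband_n_obs = scene$cband_n_obs,
                region = scene$region)
  for (i in seq_along(scene$cband_hh)) {
    bands[[paste0("cband_hh_", i)]] <- scene$cband_hh[[i]]
  }
  for (i in seq_along(scene$cband_vv)) {
    bands[[paste0("cband_vv_", i)]] <- scene$cband_vv[[i]]
  }
  for (bn in names(scene$optical)) {
    for (i in seq_along(scene$optical[[bn]])) {
      bands[[sprintf("optical_%s_%d", bn, i)]] <- scene$optical[[bn]][[i]]
    }
  }
  for (i in seq_along(scene$optical_qa)) {
    bands[[paste0("qa_", i)]] <- scene$optical_qa[[i]]
  }
  write_stack(bands, path)
  cfg <- scene$config
  cfg$sensor <- lapply(cfg$sensor, as.list)
  jsonlite::write_json(unclass(cfg), file.path(path, "scene_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
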