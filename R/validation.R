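annual_series_value <- function(series, r, x, y, buffer_m) {
  vapply(series, function(yr_raster) {
    buf <- buffer_index(yr_raster, x, y, buffer_m)
    if (nrow(buf) == 0) return(NA_real_)
    mean(unclass(yr_raster)[buf], na.rm = TRUE)
  }, numeric(1))
}

#' Filter validation sites
#'
#' Applies the field-site usability criteria: at least half the 100 m
#' buffer is forest; the annual maximum-NDVI series fluctuates (max - min)
#' by less than 0.15; both SAR polarizations fluctuate by less than 2 dB;
#' and the buffer is spatially homogeneous, i.e. the ratio of the buffer's
#' AGB standard deviation to the site AGB does not exceed 0.25. Annual
#' series are evaluated as buffer means per year. Sites outside the raster
#' extent are not evaluated; sites with zero AGB have an undefined
#' heterogeneity ratio and are excluded with a distinct audit code.
#'
#' @param sites tibble with `id`, `x`, `y`, `agb`.
#' @param forest logical `grid_raster` forest mask.
#' @param ndvi_annual list of `grid_raster`, one annual NDVI-max layer per
#'   year.
#' @param hh_annual,hv_annual annual SAR backscatter layers (dB).
#' @param agb AGB `grid_raster` used for the heterogeneity criterion.
#' @param buffer_m buffer radius (default 100 m).
#' @param forest_min minimum forest fraction (inclusive, default 0.5).
#' @param ndvi_limit NDVI fluctuation limit (strict, default 0.15).
#' @param sar_limit SAR fluctuation limit in dB (strict, default 2).
#' @param het_limit heterogeneity ratio limit (sites above it are removed,
#'   so exactly 0.25 passes; default 0.25).
#' @return list with `sites` (survivors) and `audit` (per-site criterion
#'   values, tri-state outcomes and overall status).
#' @export
filter_sites <- function(sites, forest, ndvi_annual, hh_annual, hv_annual,
                         agb, buffer_m = 100, forest_min = 0.5,
                         ndvi_limit = 0.15, sar_limit = 2,
                         het_limit = 0.25) {
  stopifnot(is.data.frame(sites), all(c("id", "x", "y", "agb") %in%
                                        names(sites)))
  audit <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    x <- sites$x[i]; y <- sites$y[i]
    rc <- gr_locate(forest, x, y)
    if (is.na(rc$row)) {
      return(tibble::tibble(id = sites$id[i], forest_fraction = NA_real_,
                            ndvi_fluct = NA_real_, hh_fluct = NA_real_,
                            hv_fluct = NA_real_, het_ratio = NA_real_,
                            forest_pass = "not_evaluated",
                            ndvi_pass = "not_evaluated",
                            sar_pass = "not_evaluated",
                            homog_pass = "not_evaluated",
                            status = "outside_extent"))
    }
    buf <- buffer_index(forest, x, y, buffer_m)
    ffrac <- mean(unclass(forest)[buf])
    nd <- annual_series_value(ndvi_annual, forest, x, y, buffer_m)
    hh <- annual_series_value(hh_annual, forest, x, y, buffer_m)
    hv <- annual_series_value(hv_annual, forest, x, y, buffer_m)
    fl <- function(v) diff(range(v, na.rm = TRUE))
    agb_sd <- stats::sd(unclass(agb)[buf], na.rm = TRUE)
    het <- if (sites$agb[i] > 0) agb_sd / sites$agb[i] else NA_real_
    pf <- function(p) if (p) "pass" else "fail"
    status <- if (sites$agb[i] <= 0) "undefined_ratio" else "evaluated"
    tibble::tibble(
      id = sites$id[i], forest_fraction = ffrac,
      ndvi_fluct = fl(nd), hh_fluct = fl(hh), hv_fluct = fl(hv),
      het_ratio = het,
      forest_pass = pf(ffrac >= forest_min),
      ndvi_pass = pf(fl(nd) < ndvi_limit),
      sar_pass = pf(fl(hh) < sar_limit && fl(hv) < sar_limit),
      homog_pass = if (is.na(het)) "not_evaluated" else pf(het <= het_limit),
      status = status)
  })
  audit$survives <- audit$status == "evaluated" &
    audit$forest_pass == "pass" & audit$ndvi_pass == "pass" &
    audit$sar_pass == "pass" & audit$homog_pass == "pass"
  list(sites = sites[audit$survives, ], audit = audit)
}

#' Map accuracy against field sites
#'
#' Pixel mode compares the map pixel under each site to the site AGB; cell
#' mode first averages both the map and the sites within square cells (the
#' grid-cell comparison used for multi-plot inventory sites).
#'
#' @param agb AGB `grid_raster`.
#' @param sites tibble with `x`, `y`, `agb`.
#' @param aggregation "pixel" (default) or "cell".
#' @param cell_size_m cell edge for cell mode (default 1000 m).
#' @param r2_method "pearson" (default) or "sse".
#' @return one-row tibble: `r2`, `rmse`, `n`.
#' @export
site_metrics <- function(agb, sites, aggregation = c("pixel", "cell"),
                         cell_size_m = 1000,
                         r2_method = c("pearson", "sse")) {
  aggregation <- match.arg(aggregation); r2_method <- match.arg(r2_method)
  if (aggregation == "pixel") {
    pred <- gr_extract(agb, sites$x, sites$y)
    obs <- sites$agb
  } else {
    ci <- cell_index(sites$x, sites$y, gr_origin(agb), cell_size_m)
    key <- paste(ci$cell_i, ci$cell_j, sep = "_")
    obs <- tapply(sites$agb, key, mean)
    cx <- tapply(sites$x, key, function(v)
      gr_origin(agb)[1] + (floor((v[1] - gr_origin(agb)[1]) / cell_size_m) +
                             0.5) * cell_size_m)
    cy <- tapply(sites$y, key, function(v)
      gr_origin(agb)[2] + (floor((v[1] - gr_origin(agb)[2]) / cell_size_m) +
                             0.5) * cell_size_m)
    pred <- cell_band_means(list(a = agb), as.numeric(cx), as.numeric(cy),
                            cell_size_m)$a
    obs <- as.numeric(obs)
  }
  ok <- is.finite(pred) & is.finite(obs)
  if (sum(ok) < 2) rlang::abort("need at least 2 comparable sites/cells")
  pred <- pred[ok]; obs <- obs[ok]
  r2 <- if (stats::sd(obs) == 0 || stats::sd(pred) == 0) NA_real_ else {
    if (r2_method == "pearson") r2_pearson(pred, obs) else r2_sse(pred, obs)
  }
  tibble::tibble(r2 = r2, rmse = sqrt(mean((pred - obs)^2)), n = sum(ok))
}

#' Map-level AGB and carbon summary
#'
#' Mean AGB over forest (non-nodata) pixels, forest area, and total
#' aboveground carbon obtained with the biomass-to-carbon fraction 0.47.
#'
#' @param agb AGB `grid_raster` (Mg ha^-1), nodata outside forest.
#' @param carbon_fraction carbon per unit dry biomass (default 0.47).
#' @return one-row tibble: `mean_agb` (Mg ha^-1), `forest_area_ha`,
#'   `total_carbon_pg` (Pg C).
#' @export
agb_to_carbon <- function(agb, carbon_fraction = 0.47) {
  v <- as.vector(unclass(agb))
  area_ha <- gr_pixel_size(agb)^2 / 1e4
  ok <- is.finite(v)
  tibble::tibble(
    mean_agb = mean(v[ok]),
    forest_area_ha = sum(ok) * area_ha,
    total_carbon_pg = sum(v[ok]) * area_ha * carbon_fraction / 1e9)
}

#' AGB histogram in 10 Mg/ha bins
#'
#' Right-closed bins labelled by their upper edge (bin "10" is (0, 10],
#' with 0 included in the first bin); relative frequencies sum to 1 over
#' forest pixels.
#'
#' @param agb AGB `grid_raster` or numeric vector; `NA` is non-forest.
#' @param bin_width bin width (default 10 Mg ha^-1).
#' @return tibble: `bin_upper`, `count`, `freq`.
#' @export
histogram_10 <- function(agb, bin_width = 10) {
  v <- as.vector(unclass(agb))
  v <- v[is.finite(v)]
  if (length(v) == 0) {
    return(tibble::tibble(bin_upper = numeric(0), count = integer(0),
                          freq = numeric(0)))
  }
  bin <- pmax(1, ceiling(v / bin_width))
  tab <- table(bin)
  tibble::tibble(bin_upper = as.integer(names(tab)) * bin_width,
                 count = as.integer(tab),
                 freq = as.integer(tab) / length(v))
}

#' Distribution of mapped AGB around field sites
#'
#' For each site and each candidate map, collects the forest pixels of the
#' 1 km x 1 km grid cell containing the site and reports median, quartiles
#' (type-7 linear interpolation) and mean — the map-comparison boxplot
#' statistics. Cells with no forest pixel in a map are excluded for that
#' map.
#'
#' @param maps named list of AGB `grid_raster`s on a shared grid.
#' @param sites tibble with `id`, `x`, `y`.
#' @param cell_size_m summary cell edge (default 1000 m).
#' @return tibble: `map`, `id`, `n_pixels`, `q1`, `median`, `q3`, `mean`.
#' @export
buffered_boxplot_stats <- function(maps, sites, cell_size_m = 1000) {
  stopifnot(length(maps) >= 1, nrow(sites) >= 1)
  tmpl <- maps[[1]]
  purrr::map_dfr(names(maps), function(nm) {
    stop_if_grid_mismatch(tmpl, maps[[nm]], what = "maps")
    purrr::map_dfr(seq_len(nrow(sites)), function(i) {
      ci <- cell_index(sites$x[i], sites$y[i], gr_origin(tmpl), cell_size_m)
      cx <- gr_origin(tmpl)[1] + (ci$cell_i + 0.5) * cell_size_m
      cy <- gr_origin(tmpl)[2] + (ci$cell_j + 0.5) * cell_size_m
      px <- gr_pixel_size(tmpl); half <- cell_size_m / 2
      rc1 <- gr_locate(tmpl, cx - half + px / 2, cy + half - px / 2)
      rc2 <- gr_locate(tmpl, cx + half - px / 2, cy - half + px / 2)
      if (is.na(rc1$row) || is.na(rc2$row)) return(NULL)
      v <- unclass(maps[[nm]])[rc1$row:rc2$row, rc1$col:rc2$col]
      v <- v[is.finite(v)]
      if (length(v) == 0) return(NULL)
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      tibble::tibble(map = nm, id = sites$id[i], n_pixels = length(v),
                     q1 = q[1], median = q[2], q3 = q[3], mean = mean(v))
    })
  })
}

#' Plot an AGB histogram
#' @param hist tibble from [histogram_10()].
#' @return a ggplot object.
#' @export
plot_agb_histogram <- function(hist) {
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$bin_upper, y = .data$freq)) +
    ggplot2::geom_col(width = diff(range(hist$bin_upper)) /
                        max(1, nrow(hist) - 1) * 0.9, fill = "forestgreen") +
    ggplot2::labs(x = "AGB bin upper edge (Mg/ha)", y = "relative frequency")
}
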