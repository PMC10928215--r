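#' SAR mosaic calibration: digital number to gamma-naught
#'
#' Converts mosaic digital numbers (DN) to terrain-normalized backscatter in
#' decibels: `gamma0 = 10 log10(DN^2) + CF`, with the mosaic calibration
#' factor `CF = -83.0 dB` by default. Non-positive DN is nodata and
#' propagates as `NA` rather than raising.
#'
#' @param dn digital number (vector, matrix or `grid_raster`).
#' @param cf calibration factor in dB (default -83.0).
#' @return gamma-naught in dB, same shape as `dn`.
#' @examples
#' dn_to_gamma0(1) # equals the calibration factor
#' @export
dn_to_gamma0 <- function(dn, cf = -83.0) {
  out <- ifelse(is.finite(dn) & dn > 0, 10 * log10(dn^2) + cf, NA_real_)
  if (inherits(dn, "grid_raster")) gr_like(dn, out) else out
}

#' @rdname dn_to_gamma0
#' @param gamma0 backscatter in dB.
#' @export
gamma0_to_dn <- function(gamma0, cf = -83.0) {
  out <- 10^((gamma0 - cf) / 20)
  if (inherits(gamma0, "grid_raster")) gr_like(gamma0, out) else out
}

#' dB / linear power conversions
#' @param db value in decibels.
#' @param lin value in linear power units.
#' @export
db_to_linear <- function(db) 10^(db / 10)

#' @rdname db_to_linear
#' @export
linear_to_db <- function(lin) 10 * log10(lin)

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  rok <- rs >= 1 & rs <= nr; cok <- cs >= 1 & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

#' Circular focal mean
#'
#' Mean over a circular neighbourhood of radius `radius_m` (pixel-centre
#' distance), the speckle filter applied to SAR mosaics before calibration.
#' Nodata pixels and the area outside the grid are excluded from each mean;
#' a pixel that is itself nodata stays nodata.
#'
#' @param r a `grid_raster` (values in the linear/power domain for SAR use).
#' @param radius_m kernel radius in metres (>= pixel size).
#' @return smoothed `grid_raster`.
#' @export
focal_mean <- function(r, radius_m = 150) {
  px <- gr_pixel_size(r)
  if (radius_m < px) rlang::abort("`radius_m` must be at least one pixel")
  k <- floor(radius_m / px)
  offs <- expand.grid(dr = -k:k, dc = -k:k)
  offs <- offs[(offs$dr^2 + offs$dc^2) * px^2 <= radius_m^2, ]
  m <- unclass(r)
  acc <- matrix(0, nrow(m), ncol(m)); cnt <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(offs))) {
    s <- shift_mat(m, offs$dr[i], offs$dc[i])
    ok <- !is.na(s)
    acc[ok] <- acc[ok] + s[ok]
    cnt[ok] <- cnt[ok] + 1
  }
  out <- acc / cnt
  out[cnt == 0 | is.na(m)] <- NA_real_
  gr_like(r, out)
}

#' Cross-polarization ratio band
#'
#' HV minus HH in dB, i.e. the linear-power HV/HH ratio expressed in
#' decibels. The ratio saturates at higher biomass than either polarization
#' alone. Nodata in either band propagates.
#'
#' @param hv_db,hh_db co-registered gamma-naught bands in dB.
#' @return `grid_raster` of HV - HH (dB).
#' @export
sar_ratio <- function(hv_db, hh_db) {
  stop_if_grid_mismatch(hv_db, hh_db, what = "SAR bands")
  gr_like(hv_db, unclass(hv_db) - unclass(hh_db))
}

stack_to_array <- function(stack) {
  stopifnot(length(stack) >= 1)
  tmpl <- stack[[1]]
  for (s in stack) stop_if_grid_mismatch(tmpl, s, what = "time-stack slices")
  arr <- array(NA_real_, c(nrow(tmpl), ncol(tmpl), length(stack)))
  for (i in seq_along(stack)) arr[, , i] <- unclass(stack[[i]])
  arr
}

#' Pooled C-band temporal statistics
#'
#' Pools HH and VV observations into one per-pixel sample and computes the
#' temporal mean, sample (n-1) standard deviation and minimum. Pixels with
#' fewer than `min_obs` pooled observations are flagged as gaps (the
#' "no-C-band" region served by a separate retrieval model).
#'
#' @param hh_stack,vv_stack lists of co-registered `grid_raster` slices; `NA`
#'   marks a missing observation.
#' @param min_obs minimum pooled observation count (default 2).
#' @return list with `grid_raster` elements `mean`, `std`, `min`, `n_obs`
#'   and logical `gap`.
#' @export
envisat_stats <- function(hh_stack, vv_stack, min_obs = 2) {
  arr <- stack_to_array(c(hh_stack, vv_stack))
  n <- apply(arr, c(1, 2), function(v) sum(!is.na(v)))
  mu <- apply(arr, c(1, 2), function(v) mean(v, na.rm = TRUE))
  sd_ <- apply(arr, c(1, 2), function(v) stats::sd(v, na.rm = TRUE))
  mn <- apply(arr, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE))
  gap <- n < min_obs
  mu[gap] <- NA_real_; sd_[gap] <- NA_real_; mn[gap] <- NA_real_
  tmpl <- hh_stack[[1]]
  list(mean = gr_like(tmpl, mu), std = gr_like(tmpl, sd_),
       min = gr_like(tmpl, mn), n_obs = gr_like(tmpl, n),
       gap = gr_like(tmpl, gap))
}

#' Normalized difference vegetation index
#' @param nir,red near-infrared and red reflectance.
#' @export
ndvi <- function(nir, red) (nir - red) / (nir + red)

#' Optical temporal composite
#'
#' Masks cloudy observations per pixel using the QA stack, then computes the
#' per-band temporal mean reflectance and the per-pixel maximum, minimum and
#' range (max - min) of NDVI across clear observations. Pixels with no clear
#' observation are nodata.
#'
#' @param band_stacks named list of time stacks (each a list of
#'   `grid_raster`); must contain `red` and `nir`.
#' @param qa_stack list of `grid_raster`, nonzero/`TRUE` = cloudy.
#' @return named list of `grid_raster`: `mean_<band>` per band plus
#'   `ndvi_max`, `ndvi_min`, `ndvi_diff`.
#' @export
landsat_composite <- function(band_stacks, qa_stack) {
  stopifnot(all(c("red", "nir") %in% names(band_stacks)))
  tmpl <- band_stacks[[1]][[1]]
  qa <- stack_to_array(qa_stack) != 0
  arrs <- lapply(band_stacks, function(s) {
    a <- stack_to_array(s)
    a[qa] <- NA_real_
    a
  })
  out <- list()
  for (nm in names(arrs)) {
    mu <- apply(arrs[[nm]], c(1, 2), function(v)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
    out[[paste0("mean_", nm)]] <- gr_like(tmpl, mu)
  }
  nd <- ndvi(arrs$nir, arrs$red)
  rng <- function(f) apply(nd, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else f(v, na.rm = TRUE))
  out$ndvi_max <- gr_like(tmpl, rng(max))
  out$ndvi_min <- gr_like(tmpl, rng(min))
  out$ndvi_diff <- gr_like(tmpl, unclass(out$ndvi_max) - unclass(out$ndvi_min))
  out
}

#' Terrain slope from a DEM
#'
#' Horn's 3x3 finite-difference slope in degrees; border cells use a
#' replicated edge.
#'
#' @param dem a `grid_raster` of elevations (m).
#' @return slope `grid_raster` (degrees, in `[0, 90)`).
#' @export
slope_from_dem <- function(dem) {
  px <- gr_pixel_size(dem)
  m <- unclass(dem)
  nr <- nrow(m); nc <- ncol(m)
  pad <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  z <- function(dr, dc) pad[seq_len(nr) + 1 + dr, seq_len(nc) + 1 + dc]
  # row index grows southwards, so +dr is -y
  dzdx <- ((z(-1, 1) + 2 * z(0, 1) + z(1, 1)) -
           (z(-1, -1) + 2 * z(0, -1) + z(1, -1))) / (8 * px)
  dzdy <- ((z(-1, -1) + 2 * z(-1, 0) + z(-1, 1)) -
           (z(1, -1) + 2 * z(1, 0) + z(1, 1))) / (8 * px)
  gr_like(dem, atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi)
}

#' Forest mask for a target year
#'
#' Forest = baseline canopy cover strictly above `threshold` percent in 2000
#' AND not flagged as lost between 2001 and the target year. `lossyear` is 0
#' for no loss, otherwise the calendar year of loss.
#'
#' @param cover2000 canopy-cover `grid_raster` (percent).
#' @param lossyear loss-year `grid_raster` (0 or year).
#' @param target_year map year (default 2007).
#' @param threshold cover threshold in percent, strict (default 10).
#' @return logical `grid_raster`.
#' @export
build_forest_mask <- function(cover2000, lossyear, target_year = 2007,
                              threshold = 10) {
  stop_if_grid_mismatch(cover2000, lossyear, what = "cover layers")
  cov <- unclass(cover2000); ly <- unclass(lossyear)
  lost <- ly > 2000 & ly <= target_year
  gr_like(cover2000, (cov > threshold & !lost))
}

#' Resample a raster to a target grid
#'
#' Continuous bands are averaged over the source pixels whose centres fall
#' in each target pixel (area-weighted block average on nested grids); masks
#' use nearest-neighbour. When a target pixel contains no source centre
#' (upsampling) the source pixel under its centre is used.
#'
#' @param r source `grid_raster`.
#' @param target `grid_raster` defining the output grid.
#' @param method "mean" (default) or "nearest".
#' @return `grid_raster` on the target grid.
#' @export
resample_to_grid <- function(r, target, method = c("mean", "nearest")) {
  method <- match.arg(method)
  es <- gr_extent(r); et <- gr_extent(target)
  if (es["xmin"] >= et["xmax"] || es["xmax"] <= et["xmin"] ||
      es["ymin"] >= et["ymax"] || es["ymax"] <= et["ymin"]) {
    rlang::abort("source and target extents do not overlap")
  }
  if (same_grid(r, target)) return(gr_like(target, unclass(r)))
  out <- matrix(NA_real_, nrow(target), ncol(target))
  if (method == "mean" && gr_pixel_size(r) <= gr_pixel_size(target)) {
    sx <- as.vector(gr_x(r)); sy <- as.vector(gr_y(r)); sv <- as.vector(r)
    rc <- gr_locate(target, sx, sy)
    ok <- !is.na(rc$row) & !is.na(sv)
    idx <- (rc$col[ok] - 1L) * nrow(target) + rc$row[ok]
    sums <- rowsum(sv[ok], idx)
    cnts <- rowsum(rep(1, sum(ok)), idx)
    out[as.integer(rownames(sums))] <- sums / cnts
  }
  # fill remaining cells (or the whole grid for nearest) from the source
  # pixel under each target centre
  need <- is.na(out)
  if (method == "nearest") need[] <- TRUE
  tx <- as.vector(gr_x(target))[need]; ty <- as.vector(gr_y(target))[need]
  out[need] <- gr_extract(r, tx, ty)
  gr_like(target, out)
}
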