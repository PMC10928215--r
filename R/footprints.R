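#' Convert footprint Lorey's heights to AGB via regional allometries
#'
#' Heights are capped at `cap_m` (footprints affected get a `CAPPED` QC
#' flag), then AGB is predicted from each footprint's regional model. The
#' cap reflects that plots with Lorey's height above 25 m are essentially
#' absent from the study domain.
#'
#' @param fp footprint tibble with columns `id`, `lorey`, `region`.
#' @param models named list of `allometric_model`, one per region level.
#' @param cap_m height cap in metres (default 25).
#' @return `fp` with `lorey` capped, `agb` added and `qc_flags` updated.
#' @export
convert_heights <- function(fp, models = list(north = allometry_north(),
                                              south = allometry_south()),
                            cap_m = 25) {
  stopifnot(is.data.frame(fp), all(c("lorey", "region") %in% names(fp)))
  unknown <- setdiff(unique(fp$region), names(models))
  if (length(unknown) > 0) {
    bad <- fp$id[fp$region %in% unknown]
    rlang::abort(sprintf("no allometric model for region(s) %s (ids: %s)",
                         paste(unknown, collapse = ", "),
                         paste(utils::head(bad, 5), collapse = ", ")))
  }
  capped <- fp$lorey > cap_m
  fp$lorey <- pmin(fp$lorey, cap_m)
  a <- unname(vapply(models, function(m) m$a, numeric(1))[fp$region])
  b <- unname(vapply(models, function(m) m$b, numeric(1))[fp$region])
  fp$agb <- a * fp$lorey^b
  fp$qc_flags <- add_flag(get_flags(fp), capped, "CAPPED")
  fp
}

`%||%` <- function(a, b) if (is.null(a)) b else a

get_flags <- function(fp) {
  if ("qc_flags" %in% names(fp)) fp$qc_flags else character(nrow(fp))
}

add_flag <- function(flags, where, flag) {
  flags[is.na(flags)] <- ""
  flags[where] <- ifelse(flags[where] == "", flag,
                         paste(flags[where], flag, sep = ";"))
  flags
}

#' Filter footprints by terrain slope
#'
#' Height retrieval degrades on slopes: footprints with slope > 15 deg are
#' removed outright, and footprints on 12-15 deg slopes are additionally
#' removed when their AGB is at most 40 Mg ha^-1, where the topographic
#' relief within a footprint is large relative to tree height. Footprints
#' with missing slope are dropped and flagged.
#'
#' @param fp footprint tibble with `slope` and `agb` columns (AGB must
#'   already be derived; see [convert_heights()]).
#' @param slope_max upper slope limit (deg, strict; default 15).
#' @param slope_band lower edge of the conditional band (deg; default 12).
#' @param agb_max AGB threshold of the conditional rule (Mg ha^-1,
#'   inclusive; default 40).
#' @return `fp` with logical `kept` and `qc_flags` columns; survivors are
#'   the rows with `kept == TRUE`.
#' @export
filter_footprints <- function(fp, slope_max = 15, slope_band = 12,
                              agb_max = 40) {
  stopifnot(is.data.frame(fp), all(c("slope", "agb") %in% names(fp)))
  flags <- get_flags(fp)
  missing_slope <- !is.finite(fp$slope)
  steep <- !missing_slope & fp$slope > slope_max
  band_low <- !missing_slope & fp$slope > slope_band &
    fp$slope <= slope_max & fp$agb <= agb_max
  flags <- add_flag(flags, steep, "SLOPE_GT15")
  flags <- add_flag(flags, band_low, "SLOPE12_15_LOWAGB")
  flags <- add_flag(flags, missing_slope, "NO_SLOPE")
  fp$qc_flags <- flags
  fp$kept <- !(steep | band_low | missing_slope)
  fp
}

cell_index <- function(x, y, origin, cell_size_m) {
  tibble::tibble(cell_i = floor((x - origin[1]) / cell_size_m),
                 cell_j = floor((y - origin[2]) / cell_size_m))
}

#' Aggregate footprints to grid cells
#'
#' Averages footprint AGB within square cells (the scale-faithful analogue
#' of the 0.01-degree aggregation that suppresses per-footprint height
#' error) and retains cells with at least `min_count` footprints. When a
#' covariate stack is supplied, each retained cell also gets the mean of
#' every band over the cell's pixels (restricted to the forest mask when
#' given).
#'
#' @param fp footprint tibble (filtered and converted; rows with a `kept`
#'   column equal to `FALSE` are ignored).
#' @param cell_size_m cell edge (m).
#' @param stack optional named list of `grid_raster` covariate bands.
#' @param forest optional logical `grid_raster` restricting band means.
#' @param min_count minimum footprints per retained cell (default 2).
#' @param agb_from "footprint" (default) converts each footprint then
#'   averages AGB; "cell_mean_height" averages Lorey's height first and
#'   converts the cell mean with the cell's majority-region model.
#' @param models regional models, needed for `agb_from = "cell_mean_height"`.
#' @return tibble: `cell_id`, `cell_x`, `cell_y` (centroid), `agb`,
#'   `n_footprints`, `region`, plus one column per band.
#' @export
aggregate_to_cells <- function(fp, cell_size_m, stack = NULL, forest = NULL,
                               min_count = 2,
                               agb_from = c("footprint", "cell_mean_height"),
                               models = list(north = allometry_north(),
                                             south = allometry_south())) {
  agb_from <- match.arg(agb_from)
  if ("kept" %in% names(fp)) fp <- fp[fp$kept, ]
  if (nrow(fp) == 0) return(tibble::tibble())
  origin <- if (!is.null(stack)) gr_origin(stack[[1]]) else c(0, 0)
  ci <- cell_index(fp$x, fp$y, origin, cell_size_m)
  fp$cell_id <- paste(ci$cell_i, ci$cell_j, sep = "_")
  majority <- function(v) names(sort(table(v), decreasing = TRUE))[1]
  cells <- fp |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      cell_x = origin[1] + (floor(min(.data$x - origin[1]) / cell_size_m) +
                              0.5) * cell_size_m,
      cell_y = origin[2] + (floor(min(.data$y - origin[2]) / cell_size_m) +
                              0.5) * cell_size_m,
      agb = mean(.data$agb),
      mean_lorey = mean(.data$lorey),
      n_footprints = dplyr::n(),
      region = majority(.data$region),
      .groups = "drop") |>
    dplyr::filter(.data$n_footprints >= min_count)
  if (agb_from == "cell_mean_height") {
    a <- unname(vapply(models, function(m) m$a, numeric(1))[cells$region])
    b <- unname(vapply(models, function(m) m$b, numeric(1))[cells$region])
    cells$agb <- a * cells$mean_lorey^b
  }
  if (!is.null(stack) && nrow(cells) > 0) {
    cells <- dplyr::bind_cols(cells,
      cell_band_means(stack, cells$cell_x, cells$cell_y, cell_size_m, forest))
  }
  cells
}

# mean of each band over the pixels of the cell centred at (cx, cy)
cell_band_means <- function(stack, cx, cy, cell_size_m, forest = NULL) {
  tmpl <- stack[[1]]
  px <- gr_pixel_size(tmpl)
  half <- cell_size_m / 2
  out <- lapply(stack, function(band) {
    vapply(seq_along(cx), function(i) {
      rc1 <- gr_locate(band, cx[i] - half + px / 2, cy[i] + half - px / 2)
      rc2 <- gr_locate(band, cx[i] + half - px / 2, cy[i] - half + px / 2)
      if (is.na(rc1$row) || is.na(rc2$row)) return(NA_real_)
      rows <- rc1$row:rc2$row; cols <- rc1$col:rc2$col
      v <- unclass(band)[rows, cols]
      if (!is.null(forest)) v[!unclass(forest)[rows, cols]] <- NA
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
  })
  tibble::as_tibble(out)
}

#' Split cells into training and validation sets
#'
#' Uniform random split with a fixed seed; the training share is
#' `round(train_frac * n)` cells.
#'
#' @param cells cell tibble from [aggregate_to_cells()].
#' @param train_frac training fraction (default 0.6).
#' @param seed integer seed.
#' @return `cells` with a `split` column in `{"train", "validation"}`.
#' @export
split_cells <- function(cells, train_frac = 0.6, seed = 1L) {
  stopifnot(nrow(cells) >= 2)
  with_seed(seed, {
    n <- nrow(cells)
    tr <- sample.int(n, round(train_frac * n))
    cells$split <- "validation"
    cells$split[tr] <- "train"
  })
  cells
}
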