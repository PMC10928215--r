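#' Stratify the forest into modelling regions
#'
#' Three mutually exclusive strata: the C-band coverage gap takes
#' precedence; remaining forest splits into flat (slope <= 10 deg) and
#' rugged (slope > 10 deg). Their union is exactly the forest mask.
#'
#' @param slope slope `grid_raster` (deg).
#' @param gap logical `grid_raster`, TRUE where C-band coverage is missing.
#' @param forest logical `grid_raster` forest mask.
#' @param slope_split stratum boundary in degrees (default 10).
#' @return list of logical `grid_raster`: `flat`, `rugged`, `no_cband`.
#' @export
stratify <- function(slope, gap, forest, slope_split = 10) {
  stop_if_grid_mismatch(slope, gap, forest, what = "strata inputs")
  f <- unclass(forest); g <- unclass(gap); s <- unclass(slope)
  list(flat = gr_like(forest, f & !g & s <= slope_split),
       rugged = gr_like(forest, f & !g & s > slope_split),
       no_cband = gr_like(forest, f & g))
}

#' Train a regional random-forest AGB model
#'
#' Fits a regression forest extrapolating cell-level GLAS-derived AGB to
#' the covariate space, with impurity ("node purity") variable importances
#' used later for pruning. Latitude and longitude are expected among the
#' features so the model can absorb broad ecoregional differences.
#'
#' @param cells cell tibble with an `agb` column and every feature column;
#'   if a `split` column is present only `"train"` rows are used.
#' @param features character vector of feature column names.
#' @param region label stored on the model.
#' @param seed integer seed (forest growth is deterministic given it).
#' @param n_trees number of trees (default 500).
#' @param mtry candidate features per split (default `ceiling(p / 3)`).
#' @return An `agb_rf_model`: region, features, importances, the fitted
#'   forest and out-of-bag diagnostics.
#' @export
train_region_model <- function(cells, features, region = "all", seed = 1L,
                               n_trees = 500, mtry = NULL) {
  missing_f <- setdiff(features, names(cells))
  if (length(missing_f) > 0) {
    rlang::abort(paste("missing feature column(s):",
                       paste(missing_f, collapse = ", ")))
  }
  train <- if ("split" %in% names(cells)) {
    cells[cells$split == "train", ]
  } else cells
  train <- train[stats::complete.cases(train[, c("agb", features)]), ]
  if (nrow(train) < 20) {
    rlang::abort("need at least 20 complete training cells")
  }
  mtry <- mtry %||% ceiling(length(features) / 3)
  dat <- as.data.frame(train[, c("agb", features)])
  fit <- ranger::ranger(
    dependent.variable.name = "agb", data = dat,
    num.trees = n_trees, mtry = min(mtry, length(features)),
    importance = "impurity", seed = seed, num.threads = 1)
  structure(list(region = region, features = features,
                 importance = fit$variable.importance,
                 fit = fit, seed = seed, n_trees = n_trees,
                 mtry = mtry, n_train = nrow(train),
                 oob_r2 = fit$r.squared, oob_mse = fit$prediction.error),
            class = "agb_rf_model")
}

#' @export
print.agb_rf_model <- function(x, ...) {
  cat(sprintf("<agb_rf_model> region %s: %d features, %d trees, n = %d\n",
              x$region, length(x$features), x$n_trees, x$n_train))
  cat(sprintf("  OOB R2 = %.3f, OOB RMSE = %.2f Mg/ha\n",
              x$oob_r2, sqrt(x$oob_mse)))
  invisible(x)
}

#' @export
tidy.agb_rf_model <- function(x, ...) {
  tibble::tibble(feature = names(x$importance),
                 node_purity = unname(x$importance)) |>
    dplyr::arrange(dplyr::desc(.data$node_purity))
}

#' @export
glance.agb_rf_model <- function(x, ...) {
  tibble::tibble(region = x$region, n_features = length(x$features),
                 n_train = x$n_train, oob_r2 = x$oob_r2,
                 oob_rmse = sqrt(x$oob_mse))
}

#' Prune low-importance variables and refit
#'
#' Drops the `k` features with smallest node purity (ties broken by stable
#' input order) and refits the forest with the same seed and
#' hyperparameters.
#'
#' @param model an `agb_rf_model`.
#' @param cells the cell table used for the original fit.
#' @param k number of features to remove (default 10); must be smaller than
#'   the current feature count.
#' @return a refitted `agb_rf_model` on the surviving features.
#' @export
prune_and_retrain <- function(model, cells, k = 10) {
  stopifnot(inherits(model, "agb_rf_model"))
  p <- length(model$features)
  if (p <= k) rlang::abort(sprintf("cannot prune %d of %d features", k, p))
  imp <- model$importance[model$features]
  drop <- model$features[order(imp, seq_along(imp))[seq_len(k)]]
  keep <- setdiff(model$features, drop)
  out <- train_region_model(cells, keep, region = model$region,
                            seed = model$seed, n_trees = model$n_trees,
                            mtry = NULL)
  out$pruned <- drop
  out
}

#' Predict a wall-to-wall AGB raster
#'
#' Applies a fitted regional model to every pixel inside the region mask,
#' reading features from stack bands of the same names. Pixels with any
#' missing feature, or outside the mask, are nodata. Predictions are
#' floored at 0.
#'
#' @param model an `agb_rf_model`.
#' @param stack named list of `grid_raster` bands covering the model
#'   features.
#' @param mask logical `grid_raster` of pixels to predict.
#' @return AGB `grid_raster` (Mg ha^-1).
#' @export
predict_map <- function(model, stack, mask) {
  missing_b <- setdiff(model$features, names(stack))
  if (length(missing_b) > 0) {
    rlang::abort(paste("stack lacks band(s):",
                       paste(missing_b, collapse = ", ")))
  }
  tmpl <- stack[[1]]
  stop_if_grid_mismatch(tmpl, mask, what = "stack and mask")
  idx <- which(unclass(mask))
  out <- matrix(NA_real_, nrow(tmpl), ncol(tmpl))
  if (length(idx) == 0) return(gr_like(tmpl, out))
  feat <- vapply(model$features, function(nm) unclass(stack[[nm]])[idx],
                 numeric(length(idx)))
  feat <- matrix(feat, nrow = length(idx),
                 dimnames = list(NULL, model$features))
  ok <- stats::complete.cases(feat)
  if (any(ok)) {
    pred <- stats::predict(model$fit,
                           data = as.data.frame(feat[ok, , drop = FALSE]),
                           num.threads = 1)$predictions
    out[idx[ok]] <- pmax(0, pred)
  }
  gr_like(tmpl, out)
}

#' Stitch per-stratum maps into one raster
#'
#' Each forest pixel takes the prediction of its stratum's map; non-forest
#' stays nodata. A forest pixel claimed by no stratum is an error.
#'
#' @param maps named list of AGB `grid_raster`s, names matching `strata`.
#' @param strata stratum list from [stratify()].
#' @param forest logical `grid_raster` forest mask.
#' @return stitched AGB `grid_raster`.
#' @export
stitch_strata <- function(maps, strata, forest) {
  stopifnot(all(names(strata) %in% names(maps)))
  tmpl <- forest
  covered <- matrix(FALSE, nrow(tmpl), ncol(tmpl))
  out <- matrix(NA_real_, nrow(tmpl), ncol(tmpl))
  for (nm in names(strata)) {
    stop_if_grid_mismatch(tmpl, strata[[nm]], maps[[nm]], what = "strata maps")
    m <- unclass(strata[[nm]])
    out[m] <- unclass(maps[[nm]])[m]
    covered <- covered | m
  }
  if (any(unclass(forest) & !covered)) {
    rlang::abort("forest pixels not claimed by any stratum")
  }
  gr_like(tmpl, out)
}

r2_pearson <- function(pred, obs) stats::cor(pred, obs)^2
r2_sse <- function(pred, obs) 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)

#' Cell-level accuracy of a predicted map
#'
#' Averages pixel predictions within each cell footprint and compares the
#' result to the cell's GLAS-derived AGB. R-squared is the squared Pearson
#' correlation by default (the scatter-plot convention); RMSE is in
#' Mg ha^-1.
#'
#' @param pred AGB `grid_raster`.
#' @param cells cell tibble with `cell_x`, `cell_y`, `agb` and optionally
#'   `split`.
#' @param cell_size_m cell edge (m).
#' @param subset which cells to score: "validation" (default, falling back
#'   to all cells when there is no `split` column), "train" or "all".
#' @param r2_method "pearson" (default) or "sse" for 1 - SSE/SST.
#' @return one-row tibble: `r2`, `rmse`, `n_cells`.
#' @export
evaluate_cells <- function(pred, cells, cell_size_m,
                           subset = c("validation", "train", "all"),
                           r2_method = c("pearson", "sse")) {
  subset <- match.arg(subset); r2_method <- match.arg(r2_method)
  if (subset != "all" && "split" %in% names(cells)) {
    cells <- cells[cells$split == subset, ]
  }
  if (nrow(cells) < 2) rlang::abort("need at least 2 cells to evaluate")
  pm <- cell_band_means(list(pred = pred), cells$cell_x, cells$cell_y,
                        cell_size_m)$pred
  ok <- is.finite(pm) & is.finite(cells$agb)
  pm <- pm[ok]; obs <- cells$agb[ok]
  r2 <- if (stats::sd(obs) == 0 || stats::sd(pm) == 0) NA_real_ else {
    if (r2_method == "pearson") r2_pearson(pm, obs) else r2_sse(pm, obs)
  }
  tibble::tibble(r2 = r2, rmse = sqrt(mean((pm - obs)^2)),
                 n_cells = sum(ok))
}
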