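#' Tree-level aboveground biomass
#'
#' China-wide tree biomass allometry: `W = 0.1355 * (D^2 H)^0.817`, with `W`
#' the oven-dry aboveground biomass of a single tree in kg, `D` the diameter
#' at breast height in cm and `H` the tree height in m.
#'
#' @param dbh diameter at breast height (cm), > 0.
#' @param height tree height (m), > 0.
#' @param a,b power-law coefficient and exponent of the tree allometry.
#' @return biomass per tree (kg), vectorized.
#' @examples
#' tree_agb(10, 10)
#' @export
tree_agb <- function(dbh, height, a = 0.1355, b = 0.817) {
  if (any(!is.finite(dbh)) || any(!is.finite(height)) ||
      any(dbh <= 0) || any(height <= 0)) {
    rlang::abort("`dbh` and `height` must be finite and positive")
  }
  a * (dbh^2 * height)^b
}

#' Plot AGB density
#'
#' Sums per-tree biomass over a plot's tree list and converts to a density
#' at the 1 ha scale.
#'
#' @param trees data frame with columns `dbh` (cm) and `height` (m).
#' @param area_ha plot area in hectares, > 0 (default 0.05, a 12.5 m-radius
#'   circular plot).
#' @return AGB density (Mg ha^-1).
#' @export
plot_agb_density <- function(trees, area_ha = 0.05) {
  stopifnot(is.data.frame(trees), all(c("dbh", "height") %in% names(trees)))
  if (nrow(trees) == 0) rlang::abort("plot must contain at least one tree")
  if (!is.finite(area_ha) || area_ha <= 0) {
    rlang::abort("`area_ha` must be positive")
  }
  sum(tree_agb(trees$dbh, trees$height)) / 1000 / area_ha
}

#' Lorey's height of a tree list
#'
#' Basal-area-weighted mean height, `sum(BA_i h_i) / sum(BA_i)` with
#' `BA_i = pi (D_i / 2)^2`. Large trees are up-weighted; the result always
#' lies between the minimum and maximum tree height, and is invariant under
#' uniform rescaling of all diameters.
#'
#' @inheritParams plot_agb_density
#' @return Lorey's height (m).
#' @export
loreys_height <- function(trees) {
  stopifnot(is.data.frame(trees), all(c("dbh", "height") %in% names(trees)))
  if (nrow(trees) == 0) rlang::abort("plot must contain at least one tree")
  ba <- pi * (trees$dbh / 2)^2
  sum(ba * trees$height) / sum(ba)
}

#' Fit a regional power-law height-to-AGB allometry
#'
#' Fits `AGB = a * Lorey^b` by nonlinear least squares on the original
#' (Mg ha^-1) scale, initialized from an ordinary least-squares fit on the
#' log-log scale. Original-scale residuals keep the reported RMSE in
#' Mg ha^-1.
#'
#' @param plots data frame with columns `lorey` (m) and `agb` (Mg ha^-1),
#'   all positive; at least 3 rows.
#' @param region region label carried on the model (e.g. "north", "south").
#' @return An `allometric_model`: list with `region`, coefficients `a`, `b`,
#'   and diagnostics `r2` (squared Pearson correlation of fitted vs observed),
#'   `rmse` (Mg ha^-1) and `n`.
#' @export
fit_power_allometry <- function(plots, region = "unlabelled") {
  stopifnot(is.data.frame(plots), all(c("lorey", "agb") %in% names(plots)))
  x <- plots$lorey; y <- plots$agb
  if (length(x) < 3) rlang::abort("need at least 3 plots to fit")
  if (any(x <= 0) || any(y <= 0)) rlang::abort("lorey and agb must be positive")
  if (length(unique(x)) < 2) {
    rlang::abort("degenerate fit: all Lorey's heights identical")
  }
  init <- stats::lm(log(y) ~ log(x))
  start <- list(a = exp(stats::coef(init)[[1]]), b = stats::coef(init)[[2]])
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * x^b, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) rlang::abort(paste("allometry fit failed:",
                                           conditionMessage(e))))
  cf <- stats::coef(fit)
  pred <- cf[["a"]] * x^cf[["b"]]
  new_allometric_model(region = region, a = cf[["a"]], b = cf[["b"]],
                       r2 = stats::cor(pred, y)^2,
                       rmse = sqrt(mean((pred - y)^2)), n = length(x))
}

new_allometric_model <- function(region, a, b, r2 = NA_real_,
                                 rmse = NA_real_, n = NA_integer_) {
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) {
    rlang::abort("allometric coefficients must be positive")
  }
  structure(list(region = region, a = a, b = b, r2 = r2, rmse = rmse, n = n),
            class = "allometric_model")
}

#' Published regional allometries
#'
#' Power-law models mapping Lorey's height (m) to AGB density (Mg ha^-1):
#' northern China `0.5014 * L^1.8762` and southern China `0.1237 * L^2.3281`.
#'
#' @return An `allometric_model`.
#' @export
allometry_north <- function() {
  new_allometric_model("north", a = 0.5014, b = 1.8762,
                       r2 = 0.75, rmse = 35.58, n = 26L)
}

#' @rdname allometry_north
#' @export
allometry_south <- function() {
  new_allometric_model("south", a = 0.1237, b = 2.3281,
                       r2 = 0.50, rmse = 22.96, n = 14L)
}

#' Predict AGB density from Lorey's height
#'
#' @param model an `allometric_model`.
#' @param lorey Lorey's height (m), >= 0; vectorized.
#' @return AGB density (Mg ha^-1); 0 maps to 0.
#' @export
predict_agb_from_lorey <- function(model, lorey) {
  stopifnot(inherits(model, "allometric_model"))
  if (any(!is.finite(lorey)) || any(lorey < 0)) {
    rlang::abort("`lorey` must be finite and nonnegative")
  }
  model$a * lorey^model$b
}

#' Invert a power allometry: AGB density to Lorey's height
#' @param model an `allometric_model`.
#' @param agb AGB density (Mg ha^-1), >= 0.
#' @return Lorey's height (m).
#' @export
lorey_from_agb <- function(model, agb) {
  stopifnot(inherits(model, "allometric_model"))
  if (any(!is.finite(agb)) || any(agb < 0)) {
    rlang::abort("`agb` must be finite and nonnegative")
  }
  (agb / model$a)^(1 / model$b)
}

#' @export
print.allometric_model <- function(x, ...) {
  cat(sprintf("<allometric_model> %s: AGB = %.4f * Lorey^%.4f\n",
              x$region, x$a, x$b))
  if (is.finite(x$r2)) {
    cat(sprintf("  fit: R2 = %.2f, RMSE = %.2f Mg/ha, n = %d\n",
                x$r2, x$rmse, as.integer(x$n)))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.allometric_model <- function(x, ...) {
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @export
glance.allometric_model <- function(x, ...) {
  tibble::tibble(region = x$region, r.squared = x$r2, rmse = x$rmse,
                 nobs = as.integer(x$n))
}
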