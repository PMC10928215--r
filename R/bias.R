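#' Fit the binned zero-intercept bias corrector
#'
#' Regression forests compress the AGB range: low-biomass cells are
#' overestimated and high-biomass cells underestimated. The corrector bins
#' the validation scatter on the reference axis in `bin_width` intervals,
#' takes per-bin means of reference and prediction, and fits a straight
#' line through the origin to the bin means:
#' `s = sum(xbar_i * ybar_i) / sum(xbar_i^2)`.
#' Dividing predictions by `s` makes the refitted bin regression coincide
#' exactly with the 1:1 line.
#'
#' @param predicted model-estimated AGB (Mg ha^-1).
#' @param reference GLAS-derived AGB (Mg ha^-1), same length.
#' @param bin_width bin width on the reference axis (default 10 Mg ha^-1).
#' @return A `bias_corrector`: slope `s`, `bin_width` and the bin table
#'   (`bin_upper`, `ref_mean`, `pred_mean`, `n`).
#' @export
fit_bias_corrector <- function(predicted, reference, bin_width = 10) {
  stopifnot(length(predicted) == length(reference))
  ok <- is.finite(predicted) & is.finite(reference)
  predicted <- predicted[ok]; reference <- reference[ok]
  bin <- pmax(1, ceiling(reference / bin_width))
  tab <- tibble::tibble(bin = bin, ref = reference, pred = predicted) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(ref_mean = mean(.data$ref),
                     pred_mean = mean(.data$pred),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$bin) |>
    dplyr::mutate(bin_upper = .data$bin * bin_width, .keep = "unused",
                  .before = 1)
  if (nrow(tab) < 2) rlang::abort("need at least 2 nonempty bins")
  s <- sum(tab$ref_mean * tab$pred_mean) / sum(tab$ref_mean^2)
  if (!is.finite(s) || s <= 0) rlang::abort("degenerate corrector slope")
  structure(list(slope = s, bin_width = bin_width, bins = tab),
            class = "bias_corrector")
}

#' Apply a bias corrector
#'
#' Global monotone rescale `corrected = value / s`; nodata and
#' nonnegativity are preserved, and the correction is idempotent in the
#' sense that refitting on corrected values (same reference bins) yields
#' slope exactly 1.
#'
#' @param corrector a `bias_corrector`.
#' @param x numeric vector or `grid_raster`.
#' @return corrected values, same shape as `x`.
#' @export
apply_bias_correction <- function(corrector, x) {
  stopifnot(inherits(corrector, "bias_corrector"))
  out <- unclass(x) / corrector$slope
  if (inherits(x, "grid_raster")) gr_like(x, out) else out
}

#' @export
print.bias_corrector <- function(x, ...) {
  cat(sprintf("<bias_corrector> slope %.4f over %d bins of %g Mg/ha\n",
              x$slope, nrow(x$bins), x$bin_width))
  invisible(x)
}

#' @export
tidy.bias_corrector <- function(x, ...) x$bins

#' @export
glance.bias_corrector <- function(x, ...) {
  tibble::tibble(slope = x$slope, bin_width = x$bin_width,
                 n_bins = nrow(x$bins))
}

#' Diagnostic plot of a bias corrector
#'
#' Bin means of predicted vs reference AGB with the zero-intercept fit and
#' the 1:1 line.
#'
#' @param x a `bias_corrector`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.bias_corrector <- function(x, ...) {
  ggplot2::ggplot(x$bins, ggplot2::aes(x = .data$ref_mean,
                                       y = .data$pred_mean)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_abline(slope = x$slope, intercept = 0, colour = "blue") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.8) +
    ggplot2::labs(x = "reference AGB, bin mean (Mg/ha)",
                  y = "predicted AGB, bin mean (Mg/ha)",
                  size = "cells")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
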