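#' Planar single-band raster
#'
#' A minimal raster container for the synthetic-scene pipeline: a numeric
#' matrix in a planar (metre) coordinate frame with an origin and a square
#' pixel size. Row 1 is the northern edge; `x` grows with column index and
#' `y` grows from the southern edge upward, so coordinates behave like map
#' coordinates. `NA` encodes nodata.
#'
#' @param values numeric matrix (rows x cols).
#' @param origin numeric length-2, planar x/y of the lower-left corner (m).
#' @param pixel_size pixel edge length in metres (default 50).
#' @return A `grid_raster` object.
#' @export
grid_raster <- function(values, origin = c(0, 0), pixel_size = 50) {
  if (!is.matrix(values)) values <- as.matrix(values)
  stopifnot(length(origin) == 2, is.finite(pixel_size), pixel_size > 0)
  structure(values,
            origin = as.numeric(origin),
            pixel_size = as.numeric(pixel_size),
            class = c("grid_raster", "matrix", "array"))
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- as.vector(x)
  cat(sprintf("<grid_raster> %d x %d px, %g m pixels, origin (%g, %g)\n",
              nrow(x), ncol(x), attr(x, "pixel_size"),
              attr(x, "origin")[1], attr(x, "origin")[2]))
  cat(sprintf("  values: min %.4g, max %.4g, NA %d\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' Grid metadata accessors
#'
#' @param r a `grid_raster`.
#' @return `gr_pixel_size()` the pixel size in metres; `gr_origin()` the
#'   lower-left corner; `gr_extent()` c(xmin, xmax, ymin, ymax).
#' @export
gr_pixel_size <- function(r) attr(r, "pixel_size")

#' @rdname gr_pixel_size
#' @export
gr_origin <- function(r) attr(r, "origin")

#' @rdname gr_pixel_size
#' @export
gr_extent <- function(r) {
  o <- gr_origin(r); px <- gr_pixel_size(r)
  c(xmin = o[1], xmax = o[1] + ncol(r) * px,
    ymin = o[2], ymax = o[2] + nrow(r) * px)
}

#' Build a raster like another, with new values
#' @param r template `grid_raster`.
#' @param values matrix or vector recycled to the template's dimensions.
#' @export
gr_like <- function(r, values) {
  m <- matrix(values, nrow = nrow(r), ncol = ncol(r))
  grid_raster(m, origin = gr_origin(r), pixel_size = gr_pixel_size(r))
}

same_grid <- function(a, b) {
  all(dim(a) == dim(b)) &&
    isTRUE(all.equal(gr_origin(a), gr_origin(b))) &&
    isTRUE(all.equal(gr_pixel_size(a), gr_pixel_size(b)))
}

stop_if_grid_mismatch <- function(..., what = "rasters") {
  rs <- list(...)
  for (i in seq_along(rs)[-1]) {
    if (!same_grid(rs[[1]], rs[[i]])) {
      rlang::abort(sprintf("%s must share grid, origin and pixel size", what))
    }
  }
  invisible(TRUE)
}

#' Pixel-centre coordinates
#'
#' @param r a `grid_raster`.
#' @return `gr_x()` / `gr_y()`: matrices of pixel-centre x / y coordinates.
#' @export
gr_x <- function(r) {
  o <- gr_origin(r); px <- gr_pixel_size(r)
  gr_like(r, matrix(o[1] + (seq_len(ncol(r)) - 0.5) * px,
                    nrow = nrow(r), ncol = ncol(r), byrow = TRUE))
}

#' @rdname gr_x
#' @export
gr_y <- function(r) {
  o <- gr_origin(r); px <- gr_pixel_size(r)
  gr_like(r, matrix(o[2] + (nrow(r) - seq_len(nrow(r)) + 0.5) * px,
                    nrow = nrow(r), ncol = ncol(r)))
}

#' Locate points on the grid
#'
#' @param r a `grid_raster`.
#' @param x,y planar coordinates.
#' @return tibble with `row`, `col` (NA when outside the extent).
#' @export
gr_locate <- function(r, x, y) {
  o <- gr_origin(r); px <- gr_pixel_size(r)
  col <- floor((x - o[1]) / px) + 1L
  row <- nrow(r) - floor((y - o[2]) / px)
  bad <- col < 1L | col > ncol(r) | row < 1L | row > nrow(r)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

#' Extract pixel values at point locations
#' @inheritParams gr_locate
#' @return numeric vector (NA outside the extent).
#' @export
gr_extract <- function(r, x, y) {
  rc <- gr_locate(r, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- r[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' @export
as_tibble.grid_raster <- function(x, ...) {
  xs <- as.vector(gr_x(x)); ys <- as.vector(gr_y(x))
  v <- as.vector(unclass(x))
  tibble::tibble(x = xs, y = ys, value = v)
}

#' Write / read a raster stack as TIFF plus a JSON sidecar
#'
#' Bands are written as one 32-bit float TIFF per band with a shared JSON
#' sidecar (`<path>/stack_manifest.json`) recording the grid origin, pixel
#' size, band names and the per-band value scaling (TIFF samples live in
#' `[0, 1]`; 0 encodes nodata).
#'
#' @param stack named list of `grid_raster` bands sharing one grid.
#' @param path output directory (created if needed).
#' @return `write_stack()` the path, invisibly; `read_stack()` the named list.
#' @export
write_stack <- function(stack, path) {
  stopifnot(length(stack) >= 1, !is.null(names(stack)))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tmpl <- stack[[1]]
  # TIFF sample values live in [0, 1]; each band is normalized on write and
  # restored on read via the scale recorded in the sidecar (0 = nodata)
  scales <- list()
  for (nm in names(stack)) {
    stop_if_grid_mismatch(tmpl, stack[[nm]], what = "stack bands")
    v <- unclass(stack[[nm]]) * 1
    fin <- is.finite(v)
    lo <- if (any(fin)) min(v[fin]) else 0
    hi <- if (any(fin)) max(v[fin]) else 1
    if (hi <= lo) hi <- lo + 1
    norm <- 0.1 + 0.9 * (v - lo) / (hi - lo)
    norm[norm > 1] <- 1
    norm[norm < 0.1] <- 0.1
    norm[!fin] <- 0
    scales[[nm]] <- c(lo = lo, hi = hi)
    tiff::writeTIFF(norm, file.path(path, paste0(nm, ".tif")),
                    bits.per.sample = 32L, reduce = FALSE)
  }
  manifest <- list(origin = gr_origin(tmpl), pixel_size = gr_pixel_size(tmpl),
                   nrow = nrow(tmpl), ncol = ncol(tmpl),
                   bands = names(stack),
                   scale_lo = vapply(scales, `[[`, numeric(1), "lo"),
                   scale_hi = vapply(scales, `[[`, numeric(1), "hi"))
  jsonlite::write_json(manifest, file.path(path, "stack_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  man <- jsonlite::read_json(file.path(path, "stack_manifest.json"),
                             simplifyVector = TRUE)
  out <- lapply(seq_along(man$bands), function(i) {
    v <- tiff::readTIFF(file.path(path, paste0(man$bands[i], ".tif")))
    lo <- man$scale_lo[i]; hi <- man$scale_hi[i]
    v[v < 0.05] <- NA_real_
    v <- lo + (v - 0.1) / 0.9 * (hi - lo)
    grid_raster(v, origin = man$origin, pixel_size = man$pixel_size)
  })
  names(out) <- man$bands
  out
}

#' Plot a raster with ggplot2
#'
#' @param r a `grid_raster`.
#' @param name legend title.
#' @return a ggplot object.
#' @export
plot_raster <- function(r, name = "value") {
  df <- as_tibble.grid_raster(r)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = name, na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}
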