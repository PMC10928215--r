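# Constructed 20-site fixture with known pass/fail labels for every
# site-filter criterion, including the threshold boundary cases:
# forest fraction exactly 1/2 (passes), fluctuation landing on the NDVI and
# SAR limits (fails, strict "less than"), and a heterogeneity ratio of
# exactly 0.25 (passes, removal requires ratio > 0.25).
#
# Sites sit on pixel corners so the 100 m buffer covers 12 pixels of the
# 50 m grid, which makes a forest fraction of exactly one half realizable.
build_site_fixture <- function() {
  nr <- 30; nc <- 120; px <- 50
  tmpl <- grid_raster(matrix(0, nr, nc), pixel_size = px)
  forest <- matrix(TRUE, nr, nc)
  years <- 6
  ndvi <- lapply(seq_len(years), function(i) matrix(0.8, nr, nc))
  hh <- lapply(seq_len(years), function(i) matrix(-7, nr, nc))
  hv <- lapply(seq_len(years), function(i) matrix(-12, nr, nc))
  agb <- matrix(80, nr, nc)

  xs <- 300 * (1:19); ys <- rep(750, 19)
  xs <- c(xs, -500); ys <- c(ys, 750)  # site 20 outside the extent
  site_agb <- rep(80, 20); site_agb[19] <- 0

  buf <- function(i) buffer_index(tmpl, xs[i], ys[i], 100)

  b9 <- buf(9); forest[b9[1:7, , drop = FALSE]] <- FALSE   # 5/12 forest
  b10 <- buf(10); forest[b10[1:6, , drop = FALSE]] <- FALSE # exactly 1/2
  b12 <- buf(12)
  for (k in seq_len(years)) ndvi[[k]][b12] <- 0.65
  ndvi[[2]][buf(11)] <- 0.60                                # fluct 0.20
  ndvi[[2]][b12] <- 0.50                                    # fluct 0.15
  ndvi[[2]][buf(13)] <- 0.71                                # fluct 0.09
  hh[[3]][buf(14)] <- -10                                   # fluct 3
  hh[[3]][buf(15)] <- -9                                    # fluct 2
  hh[[3]][buf(16)] <- -8.5; hv[[3]][buf(16)] <- -13         # 1.5 / 1
  b17 <- buf(17); agb[b17] <- 80 + c(40, -40)[1 + seq_len(nrow(b17)) %% 2]
  b18 <- buf(18); agb[b18] <- c(90, 130, 50, 50, rep(80, nrow(b18) - 4))

  gr <- function(m) grid_raster(m, pixel_size = px)
  list(
    sites = tibble::tibble(id = sprintf("s%02d", 1:20), x = xs, y = ys,
                           agb = site_agb),
    forest = gr(forest),
    ndvi_annual = lapply(ndvi, gr),
    hh_annual = lapply(hh, gr),
    hv_annual = lapply(hv, gr),
    agb = gr(agb),
    expected_survivors = sprintf("s%02d", c(1:8, 10, 13, 16, 18)),
    expected_fail = list(forest = "s09", ndvi = c("s11", "s12"),
                         sar = c("s14", "s15"), homog = "s17",
                         undefined = "s19", outside = "s20"))
}
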