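test_that("DN calibration follows the mosaic equation", {
  expect_equal(dn_to_gamma0(1), -83.0)
  # DN solving 20 log10(DN) = 83 lands on 0 dB
  expect_equal(dn_to_gamma0(10^(83 / 20)), 0)
  expect_equal(dn_to_gamma0(14125.4), 0, tolerance = 1e-4)
  # multiplying DN by 10 adds 20 dB
  expect_equal(dn_to_gamma0(3700) - dn_to_gamma0(370), 20)
  # nodata propagation, not an exception
  expect_true(is.na(dn_to_gamma0(0)))
  expect_true(is.na(dn_to_gamma0(-5)))
  # round trip through the inverse
  dn <- c(200, 5000, 14125)
  expect_equal(gamma0_to_dn(dn_to_gamma0(dn)), dn, tolerance = 1e-10)
  expect_equal(db_to_linear(linear_to_db(c(0.3, 7))), c(0.3, 7),
               tolerance = 1e-12)
})

test_that("focal mean preserves constants and kernel mass", {
  const <- grid_raster(matrix(4.2, 12, 12))
  expect_equal(vals(focal_mean(const, 150)), matrix(4.2, 12, 12))
  # a single bright pixel away from edges: kernel-weighted sum conserved
  m <- matrix(0, 15, 15); m[8, 8] <- 100
  sm <- focal_mean(grid_raster(m), 150)
  expect_equal(sum(vals(sm)) , 100, tolerance = 1e-10)
  expect_error(focal_mean(const, 10), "at least one pixel")
})

test_that("focal mean equals the naive double-loop oracle", {
  r <- rand_raster(14, 17, seed = 11, na_frac = 0.1)
  got <- vals(focal_mean(r, 150))
  want <- oracle_focal_mean(vals(r), 50, 150)
  expect_equal(got, want, tolerance = 1e-10)
  # larger kernel too
  got2 <- vals(focal_mean(r, 260))
  expect_equal(got2, oracle_focal_mean(vals(r), 50, 260), tolerance = 1e-10)
})

test_that("polarization ratio band is the dB difference", {
  hv <- grid_raster(matrix(-15, 3, 3)); hh <- grid_raster(matrix(-10, 3, 3))
  expect_equal(vals(sar_ratio(hv, hh)), matrix(-5, 3, 3))
  expect_equal(vals(sar_ratio(hh, hh)), matrix(0, 3, 3))
  # equals the linear-power ratio in dB
  a <- rand_raster(6, 6, 1); b <- rand_raster(6, 6, 2)
  expect_equal(vals(sar_ratio(a, b)),
               10 * log10(db_to_linear(vals(a)) /
                            db_to_linear(vals(b))),
               tolerance = 1e-10)
})

test_that("C-band stats pool polarizations and flag under-observed pixels", {
  g <- function(v) grid_raster(matrix(v, 1, 3), pixel_size = 50)
  hh <- list(g(c(5, 4, NA)))
  vv <- list(g(c(7, NA, NA)))
  st <- envisat_stats(hh, vv, min_obs = 2)
  expect_equal(st$mean[1, 1], 6)
  expect_equal(st$min[1, 1], 5)
  expect_equal(st$std[1, 1], sd(c(5, 7)))
  # single observation -> gap; none -> gap
  expect_true(st$gap[1, 2]); expect_true(st$gap[1, 3])
  expect_true(is.na(st$mean[1, 2]))
})

test_that("C-band stats match the per-pixel concatenation oracle", {
  set.seed(3)
  hh <- lapply(1:3, function(i) vals(rand_raster(7, 8, i, na_frac = 0.3)))
  vv <- lapply(4:5, function(i) vals(rand_raster(7, 8, i, na_frac = 0.3)))
  gh <- lapply(hh, grid_raster); gv <- lapply(vv, grid_raster)
  st <- envisat_stats(gh, gv)
  want <- oracle_envisat(hh, vv)
  expect_equal(vals(st$mean), want$mean, tolerance = 1e-10)
  expect_equal(vals(st$std), want$std, tolerance = 1e-10)
  expect_equal(vals(st$min), want$min, tolerance = 1e-10)
  expect_equal(vals(st$gap) == 1, want$gap)
})

test_that("optical composite masks clouds and reduces NDVI extremes", {
  g <- function(v) grid_raster(matrix(v, 1, 1))
  bands <- list(red = list(g(0.1), g(0.3)), nir = list(g(0.5), g(0.4)))
  qa <- list(g(0), g(1))  # second observation cloudy
  comp <- landsat_composite(bands, qa)
  expect_equal(comp$mean_red[1, 1], 0.1)
  expect_equal(comp$ndvi_max[1, 1], (0.5 - 0.1) / (0.5 + 0.1))
  expect_equal(comp$ndvi_max[1, 1], 2 / 3)
  expect_equal(comp$ndvi_diff[1, 1], 0)
  # all observations cloudy -> nodata
  comp2 <- landsat_composite(bands, list(g(1), g(1)))
  expect_true(is.na(comp2$mean_red[1, 1]))
})

test_that("optical composite matches the mask-then-reduce oracle", {
  set.seed(9)
  mk <- function(s) lapply(1:4, function(i)
    grid_raster(matrix(runif(30, 0.05, 0.6), 5, 6)))
  bands <- list(red = mk(1), nir = mk(2), swir1 = mk(3))
  qa <- lapply(1:4, function(i)
    grid_raster(matrix(rbinom(30, 1, 0.4), 5, 6)))
  comp <- landsat_composite(bands, qa)
  want <- oracle_composite(lapply(bands, lapply, unclass),
                           lapply(qa, unclass))
  expect_equal(vals(comp$mean_red), want$means$red, tolerance = 1e-10)
  expect_equal(vals(comp$mean_swir1), want$means$swir1, tolerance = 1e-10)
  expect_equal(vals(comp$ndvi_max), want$ndvi_max, tolerance = 1e-10)
  expect_equal(vals(comp$ndvi_diff), want$ndvi_diff, tolerance = 1e-10)
})

test_that("Horn slope handles planes and matches a gradient oracle", {
  flat <- grid_raster(matrix(100, 8, 8))
  expect_equal(vals(slope_from_dem(flat)), matrix(0, 8, 8))
  # plane rising 1 m per metre of x: 45 degrees away from edges
  px <- 50
  ramp <- grid_raster(matrix(rep((1:8) * px, each = 8), 8, 8), pixel_size = px)
  s <- vals(slope_from_dem(ramp))
  expect_equal(s[3:6, 3:6], matrix(45, 4, 4))
  # tilted plane a*x + b*y: analytic slope everywhere in the interior
  a <- 0.3; b <- 0.2
  xy <- grid_raster(outer(8:1, 1:8, function(r, c) a * c * px + b * r * px),
                    pixel_size = px)
  want <- atan(sqrt(a^2 + b^2)) * 180 / pi
  expect_equal(vals(slope_from_dem(xy))[2:7, 2:7],
               matrix(want, 6, 6), tolerance = 1e-8)
})

test_that("forest mask applies strict cover threshold and loss years", {
  cov <- grid_raster(matrix(c(50, 10, 50, 5, 50, 11), 1, 6))
  loss <- grid_raster(matrix(c(2005, 0, 2010, 0, 0, 0), 1, 6))
  fm <- build_forest_mask(cov, loss, target_year = 2007, threshold = 10)
  expect_equal(as.vector(vals(fm)),
               c(FALSE,  # lost in 2005 <= 2007
                 FALSE,  # cover exactly 10 fails the strict threshold
                 TRUE,   # loss in 2010 is after the target year
                 FALSE, TRUE, TRUE))
})

test_that("resampling block-averages downscale and is identity on the grid", {
  r <- rand_raster(8, 8, seed = 21, px = 50)
  expect_equal(vals(resample_to_grid(r, r)), vals(r))
  const <- grid_raster(matrix(5, 8, 8), pixel_size = 50)
  tgt <- grid_raster(matrix(0, 4, 4), pixel_size = 100)
  expect_equal(vals(resample_to_grid(const, tgt)), matrix(5, 4, 4))
  # 2x2 block average oracle on integer downsampling
  got <- vals(resample_to_grid(r, tgt))
  m <- vals(r)
  want <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    want[i, j] <- mean(m[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  }
  expect_equal(got, want, tolerance = 1e-12)
  # nearest-neighbour keeps original values
  up <- grid_raster(matrix(0, 16, 16), pixel_size = 25)
  nn <- resample_to_grid(r, up, method = "nearest")
  expect_equal(vals(nn)[1:2, 1:2], matrix(m[1, 1], 2, 2))
  far <- grid_raster(matrix(0, 4, 4), origin = c(1e6, 1e6), pixel_size = 50)
  expect_error(resample_to_grid(r, far), "overlap")
})
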