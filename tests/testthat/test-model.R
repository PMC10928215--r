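mk_cells <- function(n = 80, seed = 1, noise = 0) {
  set.seed(seed)
  x1 <- runif(n, 0, 10); x2 <- runif(n, 0, 10); x3 <- runif(n, 0, 10)
  tibble::tibble(cell_id = as.character(seq_len(n)),
                 agb = 10 * x1 + rnorm(n, 0, noise),
                 f_signal = x1, f_noise = x2, f_other = x3)
}

test_that("stratification is disjoint, exhaustive and gap-precedent", {
  slope <- grid_raster(matrix(c(5, 20, 5, 20), 2, 2))
  gap <- grid_raster(matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2))
  forest <- grid_raster(matrix(TRUE, 2, 2))
  st <- stratify(slope, gap, forest)
  expect_true(st$flat[1, 1])        # slope 5, C-band present
  expect_true(st$rugged[2, 1])      # slope 20, C-band present
  expect_true(st$no_cband[1, 2])    # gap wins regardless of slope
  expect_true(st$no_cband[2, 2])
  total <- unclass(st$flat) + unclass(st$rugged) + unclass(st$no_cband)
  expect_equal(total, unclass(forest) * 1)  # pairwise disjoint, union = forest
  # boundary: slope exactly 10 is flat
  s10 <- stratify(grid_raster(matrix(10, 1, 1)),
                  grid_raster(matrix(FALSE, 1, 1)),
                  grid_raster(matrix(TRUE, 1, 1)))
  expect_true(s10$flat[1, 1])
})

test_that("forest training learns a noiseless signal and is seed-deterministic", {
  cells <- mk_cells(100)
  cells$split <- rep(c("train", "validation"), 50)
  m <- train_region_model(cells, "f_signal", seed = 7, n_trees = 300)
  val <- cells[cells$split == "validation", ]
  pred <- predict(m$fit, data = as.data.frame(val), num.threads = 1)$predictions
  expect_gt(cor(pred, val$agb)^2, 0.95)
  m2 <- train_region_model(cells, "f_signal", seed = 7, n_trees = 300)
  pred2 <- predict(m2$fit, data = as.data.frame(val),
                   num.threads = 1)$predictions
  expect_identical(pred, pred2)
  expect_error(train_region_model(cells, c("f_signal", "nope")), "nope")
  expect_error(train_region_model(cells[1:10, ], "f_signal"), "at least 20")
})

test_that("node purity ranks an informative feature above pure noise", {
  wins <- 0
  for (sd in 1:50) {
    cells <- mk_cells(60, seed = sd, noise = 2)
    m <- train_region_model(cells, c("f_signal", "f_noise"), seed = sd,
                            n_trees = 100)
    wins <- wins + (m$importance["f_signal"] > m$importance["f_noise"])
  }
  expect_gt(wins, 25)  # majority across 50 seeds
})

test_that("pruning removes the k weakest features deterministically", {
  set.seed(11)
  n <- 60
  cells <- tibble::tibble(cell_id = as.character(1:n), agb = runif(n, 0, 100))
  cells$f_good <- cells$agb + rnorm(n, 0, 5)
  for (i in 1:14) cells[[paste0("f_junk", i)]] <- runif(n)
  feats <- c("f_good", paste0("f_junk", 1:14))
  m <- train_region_model(cells, feats, seed = 2, n_trees = 200)
  pm <- prune_and_retrain(m, cells, k = 10)
  expect_length(pm$features, 5)
  expect_true("f_good" %in% pm$features)
  expect_length(pm$pruned, 10)
  # zero-variance features carry zero importance and are always pruned
  cells$f_const <- 1
  mc <- train_region_model(cells, c(feats, "f_const"), seed = 2,
                           n_trees = 200)
  pc <- prune_and_retrain(mc, cells, k = 10)
  expect_false("f_const" %in% pc$features)
  expect_error(prune_and_retrain(pm, cells, k = 10), "cannot prune")
  # deterministic under the same seed
  pm2 <- prune_and_retrain(m, cells, k = 10)
  expect_identical(pm$features, pm2$features)
})

test_that("map prediction respects masks and matches the feature-table oracle", {
  cells <- mk_cells(80)
  m <- train_region_model(cells, c("f_signal", "f_noise"), seed = 3,
                          n_trees = 100)
  nr <- 6; nc <- 7
  set.seed(4)
  stack <- list(f_signal = grid_raster(matrix(runif(nr * nc, 0, 10), nr, nc)),
                f_noise = grid_raster(matrix(runif(nr * nc, 0, 10), nr, nc)))
  mask <- grid_raster(matrix(rep(c(TRUE, FALSE), length.out = nr * nc),
                             nr, nc))
  pred <- predict_map(m, stack, mask)
  expect_true(all(is.na(unclass(pred)[!unclass(mask)])))
  idx <- which(unclass(mask))
  df <- data.frame(f_signal = unclass(stack$f_signal)[idx],
                   f_noise = unclass(stack$f_noise)[idx])
  want <- predict(m$fit, data = df, num.threads = 1)$predictions
  expect_equal(unclass(pred)[idx], pmax(0, want))
  # empty mask -> all nodata; constant covariates -> constant prediction
  none <- grid_raster(matrix(FALSE, nr, nc))
  expect_true(all(is.na(unclass(predict_map(m, stack, none)))))
  cstack <- list(f_signal = grid_raster(matrix(5, nr, nc)),
                 f_noise = grid_raster(matrix(5, nr, nc)))
  allm <- grid_raster(matrix(TRUE, nr, nc))
  cp <- unclass(predict_map(m, cstack, allm))
  expect_equal(max(cp) - min(cp), 0)
  expect_error(predict_map(m, stack[1], mask), "lacks band")
})

test_that("stitching assigns each stratum's map without holes or overlap", {
  slope <- grid_raster(matrix(c(5, 20, 5, 20, 5, 20), 2, 3))
  gap <- grid_raster(matrix(c(rep(FALSE, 4), TRUE, TRUE), 2, 3))
  forest <- grid_raster(matrix(c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE), 2, 3))
  st <- stratify(slope, gap, forest)
  maps <- list(flat = grid_raster(matrix(1, 2, 3)),
               rugged = grid_raster(matrix(2, 2, 3)),
               no_cband = grid_raster(matrix(3, 2, 3)))
  out <- stitch_strata(maps, st, forest)
  expect_equal(out[1, 1], 1); expect_equal(out[2, 1], 2)
  expect_equal(out[1, 3], 3)
  expect_true(is.na(out[2, 3]))  # non-forest stays nodata
  # masked-sum oracle
  want <- unclass(maps$flat) * unclass(st$flat) +
    unclass(maps$rugged) * unclass(st$rugged) +
    unclass(maps$no_cband) * unclass(st$no_cband)
  got <- unclass(out); got[is.na(got)] <- 0
  expect_equal(got, want)
  # a forest pixel outside all strata is an error
  st_broken <- st
  st_broken$no_cband <- grid_raster(matrix(FALSE, 2, 3))
  expect_error(stitch_strata(maps, st_broken, forest), "not claimed")
})

test_that("cell evaluation reproduces formula oracles and edge cases", {
  cells <- tibble::tibble(cell_id = c("a", "b", "c"),
                          cell_x = c(200, 600, 1000),
                          cell_y = c(200, 200, 200),
                          agb = c(50, 100, 150))
  # build a map whose cell means equal the references exactly
  m <- matrix(NA_real_, 8, 24)
  m[1:8, 1:8] <- 50; m[1:8, 9:16] <- 100; m[1:8, 17:24] <- 150
  perfect <- grid_raster(m)
  ev <- evaluate_cells(perfect, cells, 400, subset = "all")
  expect_equal(ev$r2, 1); expect_equal(ev$rmse, 0)
  # constant offset delta -> RMSE = delta, R2 unchanged
  off <- grid_raster(m + 7)
  ev2 <- evaluate_cells(off, cells, 400, subset = "all")
  expect_equal(ev2$rmse, 7); expect_equal(ev2$r2, 1)
  # random case against the hand-rolled metric oracle
  set.seed(8)
  noisy <- grid_raster(m + rnorm(length(m), 0, 10))
  ev3 <- evaluate_cells(noisy, cells, 400, subset = "all")
  pm <- vapply(1:3, function(i)
    mean(unclass(noisy)[1:8, (8 * i - 7):(8 * i)]), numeric(1))
  want <- oracle_metrics(pm, cells$agb)
  expect_equal(ev3$r2, want$r2, tolerance = 1e-10)
  expect_equal(ev3$rmse, want$rmse, tolerance = 1e-10)
  # zero reference variance -> R2 undefined
  flat_cells <- dplyr::mutate(cells, agb = 100)
  expect_true(is.na(evaluate_cells(noisy, flat_cells, 400,
                                   subset = "all")$r2))
})
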