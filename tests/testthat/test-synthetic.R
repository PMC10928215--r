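test_that("scene generation is bit-reproducible under a fixed seed", {
  cfg <- scene_config(nrow = 40, ncol = 40, seed = 9)
  s1 <- generate_scene(cfg); s2 <- generate_scene(cfg)
  expect_identical(unclass(s1$true_agb), unclass(s2$true_agb))
  expect_identical(unclass(s1$hv_dn), unclass(s2$hv_dn))
  expect_identical(lapply(s1$cband_hh, unclass), lapply(s2$cband_hh, unclass))
  s3 <- generate_scene(scene_config(nrow = 40, ncol = 40, seed = 10))
  expect_false(identical(unclass(s1$true_agb), unclass(s3$true_agb)))
})

test_that("scene respects configured bounds and cloud settings", {
  s <- generate_scene(scene_config(nrow = 50, ncol = 50, seed = 2,
                                   cloud_fraction = 0))
  expect_true(all(unclass(s$true_agb) >= 0))
  expect_true(all(unclass(s$true_agb) <= 250))
  # the latent field spans most of the configured range
  expect_lt(min(unclass(s$true_agb)), 25)
  expect_gt(max(unclass(s$true_agb)), 225)
  expect_true(all(unclass(s$slope) >= 0 & unclass(s$slope) < 90))
  # zero cloud fraction: no observation flagged cloudy
  expect_true(all(vapply(s$optical_qa, function(q) all(unclass(q) == 0),
                         logical(1))))
  # both flat and rugged terrain present
  expect_true(any(unclass(s$slope) <= 10) && any(unclass(s$slope) > 10))
  # an under-observed C-band region exists
  expect_true(any(unclass(s$cband_n_obs) < 2))
  expect_error(scene_config(nrow = 0), "positive")
})

test_that("latent field autocorrelation at one correlation length sits in the Monte-Carlo band", {
  # band frozen from a 50-seed simulation of the 120 px default-field oracle
  s <- generate_scene(scene_config(nrow = 120, ncol = 120, corr_length = 10,
                                   seed = 31))
  m <- unclass(s$true_agb)
  ac <- cor(as.vector(m[1:110, ]), as.vector(m[11:120, ]))
  expect_gt(ac, 0.50)
  expect_lt(ac, 0.90)
})

test_that("covariates are monotone in AGB below saturation", {
  s <- generate_scene(scene_config(nrow = 80, ncol = 80, seed = 4))
  agb <- as.vector(unclass(s$true_agb))
  hv <- as.vector(unclass(dn_to_gamma0(s$hv_dn)))
  bins <- cut(agb, breaks = seq(0, 80, by = 10))  # well below k = 80
  mean_hv <- tapply(hv, bins, mean)
  expect_true(all(diff(mean_hv[!is.na(mean_hv)]) > 0))
})

test_that("footprints land on forest and carry the configured height error", {
  s <- generate_scene(scene_config(nrow = 80, ncol = 80, seed = 6))
  fp <- sample_footprints(s, 1000, seed = 3)
  rc <- gr_locate(s$forest, fp$x, fp$y)
  expect_true(all(unclass(s$forest)[cbind(rc$row, rc$col)]))
  # sample sd of the height error within chi-square-style bounds at n = 1000
  err <- fp$lorey - fp$lorey_true
  expect_gt(sd(err), 5.3); expect_lt(sd(err), 6.5)
  # zero noise inverts exactly to true AGB through the generating allometry
  s0 <- generate_scene(scene_config(nrow = 60, ncol = 60, seed = 7,
                                    height_noise_sd = 0))
  fp0 <- sample_footprints(s0, 200, seed = 4)
  models <- list(north = allometry_north(), south = allometry_south())
  back <- vapply(seq_len(200), function(i)
    predict_agb_from_lorey(models[[fp0$region[i]]], fp0$lorey[i]), numeric(1))
  expect_equal(back, fp0$agb_true, tolerance = 1e-10)
})

test_that("synthetic field plots satisfy the census threshold and identifiability", {
  p0 <- generate_field_plots("north", 12, allometry_north(), scatter = 0,
                             seed = 5)
  expect_true(all(purrr::map_lgl(p0$trees, ~ all(.x$dbh >= 5))))
  m <- fit_power_allometry(p0, "north")
  expect_equal(m$a, 0.5014, tolerance = 1e-3)
  expect_equal(m$b, 1.8762, tolerance = 1e-3)
  # realized plot quantities are self-consistent with the tree lists
  expect_equal(p0$lorey, purrr::map_dbl(p0$trees, loreys_height))
  expect_equal(p0$agb,
               purrr::map_dbl(p0$trees, plot_agb_density, area_ha = 0.05))
  expect_error(generate_field_plots("north", 1), "at least 2")
  expect_error(generate_field_plots("north", 5, scatter = -1), "nonnegative")
})

test_that("noisy plot generation recovers coefficients within the frozen Monte-Carlo CI", {
  # 99% CI from 200 replicates at n_plots = 40, scatter 0.2
  p <- generate_field_plots("north", 40, allometry_north(), scatter = 0.2,
                            seed = 17)
  m <- fit_power_allometry(p, "north")
  expect_gt(m$a, 0.118); expect_lt(m$a, 1.473)
  expect_gt(m$b, 1.498); expect_lt(m$b, 2.392)
})

test_that("validation-site generator labels match the filter module exactly", {
  s <- generate_scene(scene_config(nrow = 120, ncol = 120, seed = 8))
  sv <- generate_validation_sites(s, 20, fraction_unstable = 0.25,
                                  fraction_heterogeneous = 0.25, seed = 2)
  res <- filter_sites(sv$sites, s$forest, sv$ndvi_annual, sv$hh_annual,
                      sv$hv_annual, sv$agb)
  expect_setequal(res$sites$id, sv$sites$id[sv$sites$expect_pass])
  # per-criterion agreement, not just the overall survivor set
  audit <- res$audit[match(sv$sites$id, res$audit$id), ]
  expect_equal(audit$ndvi_pass == "pass", sv$sites$expect_ndvi)
  expect_equal(audit$homog_pass == "pass", sv$sites$expect_homog)
  # all-stable, all-homogeneous configuration survives wholesale
  sv0 <- generate_validation_sites(s, 10, 0, 0, seed = 3)
  res0 <- filter_sites(sv0$sites, s$forest, sv0$ndvi_annual, sv0$hh_annual,
                       sv0$hv_annual, sv0$agb)
  expect_equal(nrow(res0$sites), 10)
})

test_that("scene round-trips through the TIFF writer", {
  s <- generate_scene(scene_config(nrow = 20, ncol = 20, seed = 12))
  d <- withr::local_tempdir()
  write_scene(s, d)
  back <- read_stack(d)
  expect_equal(unclass(back$true_agb), unclass(s$true_agb),
               tolerance = 1e-4)
  expect_true(file.exists(file.path(d, "scene_manifest.json")))
})
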