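test_that("fixture configs carry the benchmark parameters", {
  cfg <- make_fixture("C_swelling", scale = 1)
  expect_equal(cfg$scene$R_values, seq(2.40, 2.58, by = 0.02))
  expect_identical(cfg$scene$n_spheres, 9200)
  expect_equal(cfg$scene$spacing, 5.2)
  expect_equal(cfg$walk$np, 1e6)
  expect_equal(cfg$walk$ts_us, 5)
  expect_equal(cfg$sequences$biexp$Delta_ms, 70.5)
  expect_equal(cfg$sequences$dti$n_orientations, 80)

  # the biphasic variant carries the 40 nm / slow-pool parameters
  cfgb <- make_fixture("C_swelling", biphasic = TRUE)
  expect_equal(cfgb$scene$polar$h_um, 0.04)
  expect_equal(cfgb$scene$polar$D_slow, 0.4e-3)

  # f_i sweep of the configured scenes spans 53.27% to 66.18%
  fi <- vapply(c(2.40, 2.58), function(R)
    intracellular_volume_fraction(
      make_hexagonal_sphere_lattice(cfg$scene$bounds, R, cfg$scene$spacing,
                                    n_spheres = cfg$scene$n_spheres,
                                    level = 0)), 0)
  expect_equal(fi, c(0.5327, 0.6618), tolerance = 1e-4)

  cfa <- make_fixture("A_fibers")
  sc <- scene_from_config(cfa)
  expect_identical(attr(sc, "lattice")$n, 400L)
  expect_equal(cfa$sequences[[1]]$n_orientations, 100)

  # scaling touches the walker count only, never the scene
  cfg_small <- make_fixture("B_msdi", scale = 0.04)
  cfg_full <- make_fixture("B_msdi", scale = 1)
  expect_identical(cfg_small$scene, cfg_full$scene)
  expect_equal(cfg_small$walk$np, 2e4)

  expect_error(make_fixture("B_msdi", scale = 0), "scale")
})

test_that("the swelling pipeline produces monotone ADC at reduced scale", {
  # three radii at a reduced box keep the runtime small while preserving
  # the lattice geometry; common seeds correlate the Monte Carlo error
  cfg <- make_fixture("C_swelling", scale = 2e-3, ts_us = 10)
  cfg$scene$bounds <- c(26, 26, 26)
  cfg$scene$n_spheres <- NULL
  cfg$scene$R_values <- c(2.40, 2.50, 2.58)
  cfg$walk$grid <- c(26, 26, 26)
  cfg$walk$np <- 1500
  cfg$analysis$do_biexp <- FALSE
  cfg$sequences$dti$n_orientations <- 12
  res <- run_pipeline(cfg, table = test_table())
  expect_identical(nrow(res$summary), 3L)
  expect_true(all(diff(res$summary$f_i) > 0))
  expect_true(all(diff(res$summary$adc) < 0))
  expect_true(all(res$summary$adc > 0 & res$summary$adc < 1.2e-3))
})

test_that("the MSDI pipeline emits a diffraction profile at tiny scale", {
  cfg <- make_fixture("B_msdi", scale = 1e-3, ts_us = 50)
  # shrink to a 6 x 6 sub-lattice for runtime; geometry (d, spacing) intact
  cfg$scene$rows <- 6
  cfg$scene$cols <- 6
  cfg$scene$bounds <- NULL
  cfg$scene$length <- 150
  cfg$walk$grid <- c(40, 40, 4)
  cfg$walk$np <- 800
  res <- run_pipeline(cfg, table = test_table())
  expect_identical(nrow(res$single), 121L)
  expect_equal(res$single$E[1], 1, tolerance = 1e-9)
  expect_true(all(res$single$E >= 0 & res$single$E <= 1 + 1e-9))
  expect_identical(nrow(res$double), 121L)
  # q grid: 10 mT/m increments of gamma delta G / 2 pi
  expect_equal(diff(res$single$q)[1], 8.514, tolerance = 1e-3)
})

test_that("pipelines are reproducible and seed-compatible", {
  cfg <- make_fixture("A_grid", scale = 0.02)
  cfg$walk$n_steps <- 200
  cfg$walk$grid <- c(15, 15, 15)
  res1 <- run_pipeline(cfg, table = test_table())
  res2 <- run_pipeline(cfg, table = test_table())
  expect_identical(res1$walk$positions, res2$walk$positions)

  # a different seed gives statistically compatible MSD (3 sigma overlap)
  cfg2 <- cfg
  cfg2$seeds$walk <- 99
  res3 <- run_pipeline(cfg2, table = test_table())
  m1 <- res1$msd$msd[nrow(res1$msd)]
  m3 <- res3$msd$msd[nrow(res3$msd)]
  se <- m1 * sqrt(2 / 3) / sqrt(cfg$walk$np)
  expect_lt(abs(m1 - m3), 6 * se)

  # outputs archived on request
  od <- tempfile()
  run_pipeline(cfg, outdir = od, table = test_table())
  expect_true(file.exists(file.path(od, "config.yaml")))
  expect_true(file.exists(file.path(od, "results.rds")))
  unlink(od, recursive = TRUE)
})

test_that("the HARDI pipeline synthesizes an anisotropy-bearing slice", {
  cfg <- make_fixture("D_hardi", scale = 1e-3)
  cfg$walk$np <- 1200
  cfg$walk$n_steps <- NULL
  cfg$sequences[[1]]$n_orientations <- 12
  cfg$walk$grid <- c(40, 40, 12)
  cfg$synthesis$voxel_um <- c(25, 25, NA)   # coarse voxels for the tiny walker count
  res <- run_pipeline(cfg, table = test_table())
  img <- res$image
  expect_s3_class(img, "synthetic_image")
  expect_identical(dim(img$S)[4], 12L)
  expect_equal(img$bvals, rep(4032, 12), tolerance = 0.01)
  # voxels with walkers show diffusion-weighted signal loss
  occupied <- img$S0 > 20
  expect_gt(sum(occupied), 2)
  expect_lt(mean(img$S[, , , 1][occupied] / img$S0[occupied]), 1)
})
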