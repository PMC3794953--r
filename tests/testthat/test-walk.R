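test_that("step lengths follow the 3D Einstein relation", {
  expect_equal(round(step_length(1.2e-3, 5), 2), 0.19)
  expect_equal(round(step_length(0.4e-3, 5), 2), 0.11)
  expect_identical(step_length(0, 7), 0)
  expect_error(step_length(-1e-3, 5), ">= 0")
})

test_that("free diffusion reproduces MSD = 6 D t and per-axis variance 2 D t", {
  sc <- scene(c(400, 400, 400))
  g <- build_subvolume_grid(sc, c(4, 4, 4))
  np <- 20000; D <- 2e-3; ts <- 10
  set.seed(1)
  init <- list(positions = matrix(200 + runif(np * 3, -20, 20), np, 3),
               labels = integer(np))
  wp <- walk_params(np, 500, ts, D, seed = 7, record_stride = 100)
  w <- run_walk(g, wp, init, test_table())
  msd <- trajectory_msd(w)
  for (k in seq_len(nrow(msd))) {
    t_ms <- msd$time_ms[k]
    expected <- 6 * D * 1e3 * t_ms   # um^2
    se <- expected * sqrt(2 / 3) / sqrt(np)  # |r|^2 has relative sd sqrt(2/3) (Gaussian limit)
    expect_lt(abs(msd$msd[k] - expected), 3.5 * se + 0.02 * expected)
    for (ax in c("var_x", "var_y", "var_z"))
      expect_lt(abs(msd[[ax]][k] - 2 * D * 1e3 * t_ms), 0.05 * 2 * D * 1e3 * t_ms)
  }
})

test_that("walks are bit-identical for a fixed seed and any grid dims", {
  sc <- single_sphere_scene(R = 6, box = 20)
  init <- list(positions = matrix(10 + runif(300, -5, 5), 100, 3),
               labels = integer(100))
  wp <- walk_params(100, 200, 10, 2e-3, seed = 42)
  w1 <- run_walk(build_subvolume_grid(sc, c(5, 5, 5)), wp, init, test_table())
  w2 <- run_walk(build_subvolume_grid(sc, c(5, 5, 5)), wp, init, test_table())
  w3 <- run_walk(build_subvolume_grid(sc, c(10, 10, 10)), wp, init, test_table())
  expect_identical(w1$positions, w2$positions)
  expect_identical(w1$positions, w3$positions)  # grid is an accelerator, not physics
})

test_that("particles never leave the scene and are conserved", {
  sc <- single_sphere_scene(R = 4, box = 12)
  g <- build_subvolume_grid(sc, c(6, 6, 6))
  set.seed(2)
  np <- 400L
  init <- list(positions = matrix(runif(np * 3, 0.1, 11.9), np, 3),
               labels = integer(np))
  wp <- walk_params(np, 500, 20, 2.5e-3, seed = 3)
  w <- run_walk(g, wp, init, test_table())
  expect_identical(nrow(w$positions), np)
  expect_true(all(w$positions >= 0 & w$positions <= 12))
})

test_that("membrane permeability controls transmission and label changes", {
  set.seed(4)
  np <- 500
  start <- matrix(10 + runif(np * 3, -2, 2), np, 3)

  # impermeable: labels never change, walkers stay confined
  sc0 <- single_sphere_scene(R = 4, box = 20, permeability = 0)
  g0 <- build_subvolume_grid(sc0, c(8, 8, 8))
  init <- list(positions = start, labels = rep(1L, np))
  w0 <- run_walk(g0, walk_params(np, 800, 10, 2e-3, seed = 5), init, test_table())
  expect_true(all(w0$labels == 1L))
  r <- sqrt(rowSums(sweep(w0$positions, 2, c(10, 10, 10), `-`)^2))
  expect_true(all(r <= 4 + 1e-6))

  # fully permeable: straight paths, equilibrium occupancy -> volume fraction
  sc1 <- single_sphere_scene(R = 4, box = 20, permeability = 1)
  g1 <- build_subvolume_grid(sc1, c(8, 8, 8))
  w1 <- run_walk(g1, walk_params(np, 3000, 10, 2e-3, seed = 6), init, test_table())
  f_i <- intracellular_volume_fraction(sc1)
  occ <- mean(w1$labels == 1L)
  expect_lt(abs(occ - f_i), 3.5 * sqrt(f_i * (1 - f_i) / np) + 0.01)
})

test_that("single steps obey the specular reflection law", {
  # large planar wall (two coplanar triangles, both sides) at z = 5
  wall <- triangle_mesh(rbind(c(-50, -50, 5), c(50, -50, 5), c(-50, 50, 5),
                              c(50, 50, 5)),
                        rbind(c(1, 2, 3), c(2, 4, 3), c(1, 3, 2), c(2, 3, 4)))
  sc <- scene(c(20, 20, 20), list(membrane(wall, permeability = 0)))
  g <- build_subvolume_grid(sc, c(4, 4, 4))

  # normal incidence: direction exactly reversed, total path conserved
  # travels 2 um up to the wall, reflects, travels the remaining 2 um down
  res <- advance_particle(g, c(10, 10, 3), c(0, 0, 1), 4)
  expect_equal(res$direction[1, ], c(0, 0, -1), tolerance = 1e-12)
  expect_equal(res$position[1, ], c(10, 10, 3), tolerance = 1e-6)

  # oblique incidence: angle of incidence = angle of reflection
  d_in <- c(1, 0, 1) / sqrt(2)
  res2 <- advance_particle(g, c(5, 10, 3), d_in, 6)
  expect_equal(res2$direction[1, ], c(1, 0, -1) / sqrt(2), tolerance = 1e-9)

  # permeability 1: straight through regardless of the membrane
  sc_p <- scene(c(20, 20, 20), list(membrane(wall, permeability = 1)))
  g_p <- build_subvolume_grid(sc_p, c(4, 4, 4))
  res3 <- advance_particle(g_p, c(10, 10, 3), c(0, 0, 1), 4)
  expect_equal(res3$position[1, ], c(10, 10, 7), tolerance = 1e-6)
  expect_identical(res3$label[1], 1L)   # crossed into the wall's 'interior' side
})

test_that("confined walkers plateau at the two-points-in-a-ball MSD", {
  a <- 4
  sc <- single_sphere_scene(R = a, box = 20)
  g <- build_subvolume_grid(sc, c(10, 10, 10))
  np <- 4000
  # uniform start inside the ball
  set.seed(8)
  p <- matrix(rnorm(3 * np), np, 3)
  p <- p / sqrt(rowSums(p^2)) * (a - 0.02) * runif(np)^(1 / 3)
  init <- list(positions = sweep(p, 2, c(10, 10, 10), `+`),
               labels = rep(1L, np))
  wp <- walk_params(np, 4000, 10, 2e-3, seed = 9, record_stride = 2000)
  w <- run_walk(g, wp, init, test_table())
  msd <- trajectory_msd(w)
  oracle <- two_points_in_ball_msd(a)   # brute-force sampling, = 6 a^2 / 5
  expect_equal(msd$msd[nrow(msd)], oracle, tolerance = 0.04)
})

test_that("initialization modes respect fractions, uniformity and regions", {
  sc <- make_cubic_sphere_grid(3, 3, 8, c(24, 24, 24), level = 2)
  g <- build_subvolume_grid(sc, c(8, 8, 8))

  # fractions f_i = 1: all inside
  init1 <- initialize_particles(g, particle_init("fractions", f_i = 1), 500,
                                seed = 1)
  expect_true(all(init1$labels > 0))
  expect_true(all(!is.na(locate_points(g, init1$positions))))

  # uniform: empirical intracellular fraction matches the volume fraction
  n <- 20000
  init2 <- initialize_particles(g, particle_init("uniform"), n, seed = 2)
  f_emp <- mean(init2$labels > 0)
  f_true <- intracellular_volume_fraction(sc)
  expect_lt(abs(f_emp - f_true), 3 * sqrt(f_true * (1 - f_true) / n) + 0.01)

  # region = single point
  init3 <- initialize_particles(g, particle_init("region", region = c(5, 5, 5)),
                                50, seed = 3)
  expect_true(all(init3$positions == 5))

  # f_i > 0 with no membranes rejected
  g_empty <- build_subvolume_grid(scene(c(10, 10, 10)), c(2, 2, 2))
  expect_error(initialize_particles(g_empty,
                                    particle_init("fractions", f_i = 0.5), 10),
               "no closed membranes")
})

test_that("polar residence is zero without a layer and positive with one", {
  np <- 200
  set.seed(10)
  start <- matrix(10 + runif(np * 3, -3, 3), np, 3)

  sc0 <- single_sphere_scene(R = 4, box = 20)
  w0 <- run_walk(build_subvolume_grid(sc0, c(8, 8, 8)),
                 walk_params(np, 300, 10, 1.2e-3, seed = 11),
                 list(positions = start, labels = integer(np)), test_table())
  expect_true(all(w0$polar_residence == 0))

  scp <- single_sphere_scene(R = 4, box = 20,
                             polar = list(h_um = 0.3, D_slow = 0.4e-3,
                                          D_fast = 1.2e-3))
  wp_ <- run_walk(build_subvolume_grid(scp, c(8, 8, 8)),
                  walk_params(np, 300, 10, 1.2e-3, seed = 11),
                  list(positions = start, labels = integer(np)), test_table())
  expect_gt(mean(wp_$polar_residence), 0)
  expect_true(all(wp_$polar_residence >= 0 & wp_$polar_residence <= 1))
})

test_that("parallel impermeable cylinders restrict only transverse diffusion", {
  sc <- make_hexagonal_cylinder_lattice(4, 4, 8, 8.2, 200)
  g <- build_subvolume_grid(sc, c(10, 10, 4))
  np <- 2000
  init <- initialize_particles(g, particle_init("uniform"), np, seed = 12)
  wp <- walk_params(np, 2500, 10, 2e-3, seed = 13, record_stride = 2500)
  w <- run_walk(g, wp, init, test_table())
  msd <- trajectory_msd(w)
  t_ms <- msd$time_ms[1]
  free_axis <- 2 * 2e-3 * 1e3 * t_ms
  # along the fiber axis: free diffusion; transverse: sub-linear (restricted)
  expect_gt(msd$var_z[1], 0.9 * free_axis)
  expect_lt(msd$var_x[1], 0.65 * free_axis)
  expect_lt(msd$var_y[1], 0.65 * free_axis)
})
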