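test_that("phase accumulation: stationary, zero-gradient, and moving spins", {
  wf <- build_pgse(40, 10, 20, ts_us = 10)
  # zero gradient
  wf0 <- build_pgse(0, 10, 20, ts_us = 10)
  traj <- matrix(rep(c(1, 2, 3), each = wf$n_steps), wf$n_steps, 3)
  expect_equal(accumulate_phase(traj, wf0), 0)
  expect_lt(abs(accumulate_phase(traj, wf)), 1e-9)

  # constant velocity v along the gradient: phi = gamma G v delta Delta + O(ts)
  v <- 0.02   # um/us = mm/ms
  ts <- 5
  wf_v <- build_pgse(30, 8, 16, ts_us = ts)
  tt <- seq_len(wf_v$n_steps) * ts          # us
  traj_v <- cbind(v * tt, 0 * tt, 0 * tt)   # um
  phi <- accumulate_phase(traj_v, wf_v)
  # |phi| = gamma G v delta Delta; v in um/us = m/s
  phi_expected <- 2.675e8 * 30e-3 * 0.02 * 8e-3 * 16e-3
  expect_equal(abs(phi), phi_expected, tolerance = 5e-3)
})

test_that("array and matrix phase accumulation agree with the online engine", {
  sc <- scene(c(100, 100, 100))
  g <- build_subvolume_grid(sc, c(4, 4, 4))
  np <- 50
  set.seed(20)
  init <- list(positions = matrix(50 + runif(np * 3, -5, 5), np, 3),
               labels = integer(np))
  wf <- build_pgse(40, 2, 6, ts_us = 20, orientation = c(1, 1, 0))
  wp <- walk_params(np, wf$n_steps, 20, 2e-3, seed = 21, record_stride = 1)
  w <- run_walk(g, wp, init, test_table(), list(wf))
  phi_offline <- accumulate_phase(w$trajectory, wf)
  expect_equal(phi_offline, w$phases[, 1], tolerance = 1e-10)
  phi_one <- accumulate_phase(t(w$trajectory[7, , ]), wf)
  expect_equal(phi_one, w$phases[7, 1], tolerance = 1e-10)
})

test_that("free-diffusion attenuation matches exp(-bD) across b-values", {
  sc <- scene(c(400, 400, 400))
  g <- build_subvolume_grid(sc, c(4, 4, 4))
  np <- 1e5
  D <- 2e-3
  set.seed(22)
  init <- list(positions = matrix(200 + runif(np * 3, -50, 50), np, 3),
               labels = integer(np))
  ts <- 20
  wf_ref <- build_pgse(150, 5, 11, ts_us = ts, S_R = 5000)   # the b = 2e3 end
  b_ref <- compute_bvalue(wf_ref)
  wp <- walk_params(np, wf_ref$n_steps, ts, D, seed = 23)
  w <- run_walk(g, wp, init, test_table(), list(wf_ref))
  for (b_target in c(500, 1000, 2000)) {
    f <- sqrt(b_target / b_ref)
    E <- Mod(sum(exp(-1i * w$phases[, 1] * f))) / np
    E_true <- exp(-b_target * D)
    se <- sqrt((1 - E_true^2) / (2 * np))
    expect_lt(abs(E - E_true), 3 * se + 0.01 * E_true + 1 / sqrt(np))
  }
})

test_that("fast/slow pool segregation partitions walkers monotonically", {
  res <- c(0, 0.1, 0.2, 0.49, 0.5, 0.8, 1)
  sets <- segregate_fast_slow(res, 0.5)
  expect_identical(sort(c(sets$fast, sets$slow)), seq_along(res))
  expect_identical(sets$slow, c(5L, 6L, 7L))
  # threshold sweep: slow set monotonically non-increasing
  sizes <- vapply(seq(0, 1, by = 0.1), function(th)
    length(segregate_fast_slow(res, th)$slow), 0L)
  expect_true(all(diff(sizes) <= 0))
  expect_error(segregate_fast_slow(res, 1.5), "threshold")
  # all walkers far from membranes: slow set empty
  expect_length(segregate_fast_slow(rep(0, 10), 0.5)$slow, 0)
})

test_that("voxel signals integrate phasors with the expected noise behavior", {
  vg <- voxel_grid(c(2, 2, 1), c(5, 5, 10))
  set.seed(24)
  pos <- cbind(runif(400, 0, 10), runif(400, 0, 10), runif(400, 0, 10))
  # all phases zero, no noise: S = S0 = count
  vs <- voxel_signal(rep(0, 400), pos, vg, sigma = 0)
  expect_equal(vs$S, vs$counts)
  expect_equal(vs$S0, vs$counts)
  expect_equal(sum(vs$counts), 400)

  # noise-free S <= S0 for any phases (triangle inequality)
  ph <- runif(400, -pi, pi)
  vs2 <- voxel_signal(ph, pos, vg, sigma = 0)
  expect_true(all(vs2$S <= vs2$S0 + 1e-12))

  # global phase offset leaves S/S0 invariant
  vs3 <- voxel_signal(ph + 1.234, pos, vg, sigma = 0)
  expect_equal(vs3$S, vs2$S, tolerance = 1e-12)

  # zero particles with noise: Rayleigh floor sigma sqrt(pi/2)
  vg_big <- voxel_grid(c(40, 40, 10), c(1, 1, 1))
  vs4 <- voxel_signal(numeric(0), matrix(0, 0, 3), vg_big, sigma = 2, seed = 9)
  expect_equal(mean(vs4$S), 2 * sqrt(pi / 2), tolerance = 0.02)

  expect_error(voxel_signal(0, matrix(1, 1, 3), vg, sigma = -1), "sigma")
})

test_that("fast/slow complex sub-signals sum to the global signal", {
  set.seed(25)
  ph <- runif(1000, -pi, pi)
  res <- runif(1000)
  sets <- segregate_fast_slow(res, 0.5)
  z_all <- sum(exp(-1i * ph))
  z_split <- sum(exp(-1i * ph[sets$fast])) + sum(exp(-1i * ph[sets$slow]))
  expect_equal(z_all, z_split, tolerance = 1e-12)
})

test_that("image synthesis is deterministic and anisotropy-sensitive", {
  sc <- make_hexagonal_cylinder_lattice(3, 3, 8, 8.2, 120)
  g <- build_subvolume_grid(sc, c(8, 8, 4))
  np <- 3000
  init <- initialize_particles(g, particle_init("uniform"), np, seed = 26)
  ts <- 20
  wf_par <- build_pgse(300, 3, 10, ts_us = ts, S_R = 5000,
                       orientation = c(0, 0, 1))
  wf_perp <- rotate_waveform(wf_par, c(1, 0, 0))
  wp <- walk_params(np, wf_par$n_steps, ts, 2e-3, seed = 27)
  w <- run_walk(g, wp, init, test_table(), list(wf_par, wf_perp))
  E <- bulk_attenuation(w)
  # more signal loss along the unrestricted fiber axis
  expect_lt(E[1], E[2])

  vg <- voxel_grid(c(3, 3, 1), c(sc$bounds[1] / 3, sc$bounds[2] / 3,
                                 sc$bounds[3]))
  img1 <- synthesize_image(w, vg, sigma = 0.5, seed = 31)
  img2 <- synthesize_image(w, vg, sigma = 0.5, seed = 31)
  expect_identical(img1$S, img2$S)
  img3 <- synthesize_image(w, vg, sigma = 0.5, seed = 32)
  expect_false(identical(img3$S, img1$S))

  # sigma = 0: image equals the per-voxel phasor magnitudes; S0 = counts
  img0 <- synthesize_image(w, vg, sigma = 0)
  vs <- voxel_signal(w$phases[, 1], w$positions, vg, sigma = 0)
  expect_equal(as.vector(img0$S[, , , 1]), as.vector(vs$S))
  expect_equal(as.vector(img0$S0), as.vector(vs$counts))

  f <- tempfile(fileext = ".nii.gz")
  write_image_nifti(img0, f)
  back <- RNifti::readNifti(f)
  expect_equal(dim(back), dim(img0$S))
  unlink(f)
})
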