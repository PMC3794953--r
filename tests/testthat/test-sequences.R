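test_that("every sequence family satisfies the echo condition", {
  ts <- 10
  wfs <- list(
    build_pgse(40, 20, 30, ts, S_R = 200),
    build_pgse(40, 20, 30, ts),                          # rectangle
    build_multiple_pgse(40, 5, 40, T_M_ms = 10, N_GP = 2, ts_us = ts, S_R = 500),
    build_ste_family("STE", 40, 10, 40, T_M_ms = 20, ts_us = ts, S_R = 200),
    build_ste_family("bipolar-STE", 40, 10, 40, ts_us = ts, S_R = 200),
    build_ste_family("bipolar-double-STE", 40, 5, 30, T_M_ms = 15, ts_us = ts,
                     S_R = 500),
    build_trse(40, 10, 15, 10, 15, ts, S_R = 200),
    build_ogse(40, 10, 3, "cosine", ts),
    build_ogse(40, 10, 3, "sine", ts),
    build_ogse(40, 10, 2, "double_sine", ts))
  for (wf in wfs) {
    m0 <- sum(wf$shape) * wf$ts_us * 1e-6
    expect_lt(abs(m0), 1e-15)
    # stationary spin accumulates zero phase under any balanced waveform
    traj <- matrix(rep(c(3, -2, 7), each = wf$n_steps), wf$n_steps, 3)
    expect_lt(abs(accumulate_phase(traj, wf)), 1e-9)
    expect_gte(compute_bvalue(wf), 0)
  }
})

test_that("PGSE b-values match the Stejskal-Tanner closed form", {
  # rectangle, fine sampling: < 0.1%
  wf <- build_pgse(40, 21, 27, ts_us = 5)
  expect_equal(compute_bvalue(wf), stejskal_tanner_b(40, 21, 27),
               tolerance = 1e-3)
  # trapezoid with ramps
  wf2 <- build_pgse(40, 34.75, 40.75, ts_us = 5, S_R = 200, TE_ms = 80)
  expect_equal(compute_bvalue(wf2), stejskal_tanner_b(40, 34.75, 40.75, 200),
               tolerance = 1e-3)
  # G = 0 -> b = 0
  expect_equal(compute_bvalue(build_pgse(0, 10, 20, 10)), 0)
})

test_that("the two benchmark timings give b of 1,000 and 4,000 s/mm^2", {
  b_shell <- compute_bvalue(build_pgse(40, 21, 27, ts_us = 5, S_R = 200))
  expect_equal(b_shell, 1000, tolerance = 0.01)
  b_hardi <- compute_bvalue(build_pgse(40, 34.75, 40.75, ts_us = 5, S_R = 200,
                                       TE_ms = 80))
  expect_equal(b_hardi, 4000, tolerance = 0.01)
})

test_that("b scales with the square of the gradient amplitude", {
  for (make in list(
    function(G) build_pgse(G, 10, 20, 10),
    function(G) build_multiple_pgse(G, 4, 25, 5, 2, 10),
    function(G) build_trse(G, 8, 12, 8, 12, 10),
    function(G) build_ogse(G, 8, 2, "cosine", 10))) {
    Gs <- c(10, 20, 30, 40, 50)
    bs <- vapply(Gs, function(G) compute_bvalue(make(G)), 0)
    fit <- lm(bs ~ I(Gs^2))
    expect_gt(summary(fit)$r.squared, 1 - 1e-9)
    expect_lt(abs(coef(fit)[1]) / max(bs), 1e-6)
  }
})

test_that("multiple PGSE doubles the single-PGSE b at matched parameters", {
  b1 <- compute_bvalue(build_pgse(60, 4, 30, ts_us = 5))
  b2 <- compute_bvalue(build_multiple_pgse(60, 4, 30, T_M_ms = 0, N_GP = 2,
                                           ts_us = 5))
  expect_equal(b2, 2 * b1, tolerance = 1e-6)
})

test_that("STE degenerates to PGSE as the storage interval vanishes", {
  wf_ste <- build_ste_family("STE", 40, 10, 30, T_M_ms = 0, ts_us = 10,
                             S_R = 200)
  wf_pgse <- build_pgse(40, 10, 30, ts_us = 10, S_R = 200)
  expect_equal(wf_ste$shape, wf_pgse$shape)
  # bipolar STE b equals monopolar at the same (G, delta, Delta)
  b_bip <- compute_bvalue(build_ste_family("bipolar-STE", 40, 10, 30,
                                           ts_us = 10, S_R = 200))
  expect_equal(b_bip, compute_bvalue(wf_pgse), tolerance = 1e-9)
})

test_that("TRSE validates the echo condition and matches its PGSE-equivalent b", {
  expect_error(build_trse(40, 10, 12, 10, 15, 10), "echo condition")
  # equal lobes d: effective k(t) is triangle-shaped; closed form equals a
  # PGSE with delta = d and Delta = 5 d / 3
  d <- 8
  b_trse <- compute_bvalue(build_trse(40, d, d, d, d, ts_us = 5))
  expect_equal(b_trse, stejskal_tanner_b(40, d, 5 * d / 3), tolerance = 1e-3)
})

test_that("cosine OGSE matches its closed-form b and b falls with frequency", {
  G <- 60; Tp <- 8; N <- 3; ts <- 2
  wf <- build_ogse(G, Tp, N, "cosine", ts)
  omega <- 2 * pi / (Tp * 1e-3)
  b_lobe <- (2.675e8)^2 * (G * 1e-3)^2 * (N * Tp * 1e-3) / (2 * omega^2)
  expect_equal(compute_bvalue(wf), 2 * b_lobe * 1e-6, tolerance = 2e-3)

  # fixed G and total duration: b decreases monotonically with frequency
  bs <- vapply(1:4, function(k)
    compute_bvalue(build_ogse(G, 24 / k, k, "cosine", ts)), 0)
  expect_true(all(diff(bs) < 0))

  expect_error(build_ogse(40, 10, 1.5, "cosine", 10), "whole number")
})

test_that("q-values follow gamma delta G / 2 pi", {
  wf <- build_pgse(770, 2, 200, ts_us = 20, S_R = 5000)
  expect_equal(compute_q(wf), 655.6, tolerance = 1e-3)
  expect_equal(compute_q(build_pgse(0.0, 2, 200, 20)), 0)
  # doubling delta doubles q
  expect_equal(compute_q(build_pgse(100, 4, 200, 20)),
               2 * compute_q(build_pgse(100, 2, 200, 20)), tolerance = 1e-12)
  # double PGSE plotted against 2q
  wfd <- build_multiple_pgse(385, 2, 200, 0, 2, ts_us = 20, S_R = 5000)
  expect_equal(compute_q(wfd, effective = TRUE), 2 * compute_q(wfd),
               tolerance = 1e-12)
})

test_that("waveform timing violations are rejected", {
  expect_error(build_pgse(40, 30, 20, 10), "delta must not exceed Delta")
  expect_error(build_pgse(40, 20, 30, 10, TE_ms = 40), "overflow")
  expect_error(build_pgse(400, 1, 30, 10, S_R = 200), "ramp time")
})

test_that("scheme export writes FSL-style bval/bvec files", {
  wfs <- list(build_pgse(40, 10, 20, 10, orientation = c(1, 0, 0)),
              build_pgse(40, 10, 20, 10, orientation = c(0, 1, 1)))
  pre <- tempfile()
  write_scheme(wfs, pre)
  bv <- scan(paste0(pre, ".bval"), quiet = TRUE)
  expect_equal(bv[1], bv[2], tolerance = 1e-9)
  vecs <- as.matrix(read.table(paste0(pre, ".bvec")))
  expect_equal(dim(vecs), c(3L, 2L))
  expect_equal(vecs[, 2], c(0, 1, 1) / sqrt(2), tolerance = 1e-6,
               ignore_attr = TRUE)
  unlink(paste0(pre, c(".bval", ".bvec")))
})
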