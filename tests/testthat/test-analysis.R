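test_that("tensor fits recover forward models exactly", {
  dirs <- uniform_orientations(30, seed = 3)
  b <- rep(1000, nrow(dirs))

  # isotropic: ADC = D, FA = 0
  D <- 1.7e-3
  E_iso <- exp(-b * D)
  fit <- fit_diffusion_tensor(E_iso, b, dirs)
  expect_equal(fit$adc, D, tolerance = 1e-6)
  expect_lt(fit$fa, 1e-6)

  # known anisotropic SPD tensor recovered to solver tolerance
  R <- qr.Q(qr(matrix(c(1, 2, 3, 0, 1, 1, 1, 0, 2), 3, 3)))
  Dt <- R %*% diag(c(1.8e-3, 0.4e-3, 0.2e-3)) %*% t(R)
  E <- exp(-b * rowSums((dirs %*% Dt) * dirs))
  fit2 <- fit_diffusion_tensor(E, b, dirs)
  expect_equal(fit2$tensor, Dt, tolerance = 1e-9)
  expect_true(fit2$fa > 0 && fit2$fa <= 1)

  # rank-deficient design rejected
  collinear <- matrix(rep(c(1, 0, 0), 8), ncol = 3, byrow = TRUE)
  expect_error(fit_diffusion_tensor(exp(-1000 * 1e-3 * rep(1, 8)),
                                    rep(1000, 8), collinear),
               "rank-deficient")
})

test_that("biexponential fits recover noise-free forward parameters", {
  b <- seq(0, 5000, length.out = 51)
  truth <- c(F_f = 0.5, D_f = 0.9e-3, F_s = 0.5, D_s = 0.01e-3)
  E <- truth["F_f"] * exp(-b * truth["D_f"]) + truth["F_s"] * exp(-b * truth["D_s"])
  fit <- fit_biexponential(E, b)
  expect_equal(unname(fit$mean["F_f"]), 0.5, tolerance = 1e-6)
  expect_equal(unname(fit$mean["D_f"]), 0.9e-3, tolerance = 1e-6)
  expect_equal(unname(fit$mean["F_s"]), 0.5, tolerance = 1e-6)
  expect_equal(unname(fit$mean["D_s"]), 0.01e-3, tolerance = 1e-4)

  # parameter recovery bias < 2% over a parameter sweep on the same b grid
  for (Ff in c(0.35, 0.6)) {
    for (Df in c(0.7e-3, 1.1e-3)) {
      tr <- c(Ff, Df, 1 - Ff, 0.008e-3)
      E2 <- tr[1] * exp(-b * tr[2]) + tr[3] * exp(-b * tr[4])
      f2 <- fit_biexponential(E2, b)
      expect_lt(abs(f2$mean["F_f"] - tr[1]) / tr[1], 0.02)
      expect_lt(abs(f2$mean["D_f"] - tr[2]) / tr[2], 0.02)
      expect_lt(abs(f2$mean["F_s"] - tr[3]) / tr[3], 0.02)
    }
  }

  # per-axis summary: mean and sd across three identical axes
  fit3 <- fit_biexponential(cbind(E, E, E), b)
  expect_equal(nrow(fit3$per_axis), 3L)
  expect_equal(unname(fit3$sd["F_f"]), 0, tolerance = 1e-8)

  # b = 0 anchors the fractions near unity for well-posed decays
  expect_equal(unname(fit$mean["F_f"] + fit$mean["F_s"]), 1, tolerance = 1e-4)
})

test_that("diffraction troughs are detected on raw samples only", {
  # free diffusion: monotone profile, no trough
  q <- seq(0, 1000, by = 8.5)
  E_free <- exp(-1e-5 * q^2)
  expect_message(res <- detect_diffraction_trough(q, E_free), "no diffraction")
  expect_null(res)

  # |sinc|^2-shaped profile: trough at the sample nearest the true zero
  q0 <- 655.7
  E_sinc <- (sin(pi * q / q0) / (pi * q / q0))^2
  E_sinc[1] <- 1
  res2 <- detect_diffraction_trough(q, E_sinc)
  expect_equal(res2$q_star, q[which.min(abs(q - q0))])

  # the first local minimum is returned even when later ones are deeper
  E_two <- 0.5 * (cos(q / 60) + 1.01) * exp(-q / 800)
  res3 <- detect_diffraction_trough(q, E_two)
  first_min <- which(diff(sign(diff(E_two))) > 0)[1] + 1
  expect_identical(res3$index, as.integer(first_min))
})

test_that("the Callaghan relation maps trough position to pore diameter", {
  expect_equal(estimate_diameter_callaghan(655.7), 18.6, tolerance = 1e-3)
  expect_equal(estimate_diameter_callaghan(1.22e4), 1.0)
  expect_equal(estimate_diameter_callaghan(610), 20.0)
  expect_error(estimate_diameter_callaghan(0), "positive")
})
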