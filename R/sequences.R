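# Effective gradient waveforms for the diffusion pulse-sequence catalogue.
#
# A waveform is sampled on the walk's time base: step i carries the interval
# average of the analytic effective gradient over [(i-1) t_s, i t_s], so the
# echo condition (zero zeroth moment) holds to machine precision and phase
# sums and b-value quadrature share one time grid. "Effective" means the
# refocusing-pulse sign flips are folded into the gradient sign.

# --- analytic components: each knows its cumulative integral F(t) = int g dt
comp_const <- function(t0, t1, g) {
  force(t0); force(t1); force(g)
  function(t) g * (pmin(pmax(t, t0), t1) - t0)
}
comp_ramp <- function(t0, t1, g0, g1) {
  force(t0); force(t1); force(g0); force(g1)
  function(t) {
    tau <- pmin(pmax(t, t0), t1) - t0
    g0 * tau + (g1 - g0) * tau^2 / (2 * (t1 - t0))
  }
}
comp_sin <- function(t0, t1, G, Tp) {
  function(t) {
    tau <- pmin(pmax(t, t0), t1) - t0
    G * Tp / (2 * pi) * (1 - cos(2 * pi * tau / Tp))
  }
}
comp_cos <- function(t0, t1, G, Tp) {
  function(t) {
    tau <- pmin(pmax(t, t0), t1) - t0
    G * Tp / (2 * pi) * sin(2 * pi * tau / Tp)
  }
}

# trapezoid lobe: delta spans ramp-up start to ramp-down start (includes one
# ramp); eps = G/S_R. A rectangle is the eps = 0 limit.
trap_lobe <- function(t0, delta, eps, g) {
  if (eps <= 0) return(list(comp_const(t0, t0 + delta, g)))
  list(comp_ramp(t0, t0 + eps, 0, g),
       comp_const(t0 + eps, t0 + delta, g),
       comp_ramp(t0 + delta, t0 + delta + eps, g, 0))
}

waveform_from_components <- function(comps, ts_us, te_ms, rf_times_ms, family,
                                     amplitude, orientation, params) {
  ts_ms <- ts_us * 1e-3
  n <- as.integer(ceiling(te_ms / ts_ms - 1e-9))
  tg <- (0:n) * ts_ms
  Fv <- rowSums(vapply(comps, function(f) f(tg), numeric(n + 1)))
  shape <- diff(Fv) / ts_ms
  orientation <- orientation / sqrt(sum(orientation^2))
  structure(list(family = family, ts_us = ts_us, n_steps = n, te_ms = te_ms,
                 shape = shape, orientation = orientation,
                 amplitude = amplitude, rf_times_ms = rf_times_ms,
                 params = params),
            class = "gradient_waveform")
}

#' @export
print.gradient_waveform <- function(x, ...) {
  cat(sprintf("gradient_waveform [%s]: TE %.3g ms, %d steps of %g us, peak |G| %.3g mT/m, b = %.4g s/mm^2\n",
              x$family, x$te_ms, x$n_steps, x$ts_us, 1e3 * x$amplitude,
              compute_bvalue(x)))
  invisible(x)
}

check_rf_window <- function(rf, busy_iv) {
  for (iv in busy_iv)
    if (rf > iv[1] - 1e-9 && rf < iv[2] + 1e-9)
      stop("refocusing pulse collides with a gradient lobe; adjust TE")
}

#' Pulsed-gradient spin-echo (PGSE) effective waveform
#'
#' Two matched diffusion lobes of duration `delta` separated by `Delta`
#' (leading edge to leading edge) around one refocusing pulse at TE/2; the
#' effective waveform flips sign after the pulse. With a finite slew rate the
#' lobes are trapezoids with ramp time `eps = G/S_R`; `delta` spans ramp-up
#' start to ramp-down start (it includes one ramp), so the lobe occupies
#' `delta + eps` of wall time.
#'
#' @param G gradient magnitude (mT/m)
#' @param delta_ms gradient duration (ms)
#' @param Delta_ms gradient separation (ms)
#' @param ts_us sampling time step (us), matching the walk
#' @param S_R slew rate (T/m/s); `Inf` gives rectangular lobes
#' @param TE_ms echo time (ms); computed automatically when `NULL`
#' @param orientation gradient direction (normalized internally)
#' @param t_start_ms start of the first lobe (ms)
#' @return a `gradient_waveform`
#' @export
build_pgse <- function(G, delta_ms, Delta_ms, ts_us = 10, S_R = Inf,
                       TE_ms = NULL, orientation = c(1, 0, 0), t_start_ms = 0) {
  if (delta_ms > Delta_ms) stop("delta must not exceed Delta")
  g <- G * 1e-3
  eps <- if (is.finite(S_R)) g / S_R * 1e3 else 0
  if (eps >= delta_ms) stop("ramp time G/S_R must be shorter than delta")
  lobe_end1 <- t_start_ms + delta_ms + eps
  lobe_start2 <- t_start_ms + Delta_ms
  lobe_end2 <- lobe_start2 + delta_ms + eps
  if (lobe_end1 > lobe_start2) stop("lobes overlap: Delta < delta + ramp")
  if (is.null(TE_ms)) TE_ms <- max(lobe_end2, 2 * lobe_end1)
  if (lobe_end2 > TE_ms + 1e-9) stop("timing overflow beyond TE")
  rf <- TE_ms / 2
  check_rf_window(rf, list(c(t_start_ms, lobe_end1), c(lobe_start2, lobe_end2)))
  comps <- c(trap_lobe(t_start_ms, delta_ms, eps, g),
             trap_lobe(lobe_start2, delta_ms, eps, -g))
  waveform_from_components(comps, ts_us, TE_ms, rf, "PGSE", g, orientation,
                           list(G = G, S_R = S_R, delta_ms = delta_ms,
                                Delta_ms = Delta_ms))
}

#' Multiple PGSE effective waveform
#'
#' `N_GP` concatenated PGSE blocks sharing one echo, with a mixing time `T_M`
#' between consecutive blocks; each block carries its own refocusing pulse so
#' each block's effective lobes cancel pairwise.
#'
#' @inheritParams build_pgse
#' @param T_M_ms mixing time between gradient pairs (ms)
#' @param N_GP number of gradient pairs (>= 2)
#' @return a `gradient_waveform`
#' @export
build_multiple_pgse <- function(G, delta_ms, Delta_ms, T_M_ms = 0, N_GP = 2,
                                ts_us = 10, S_R = Inf, TE_ms = NULL,
                                orientation = c(1, 0, 0)) {
  if (N_GP < 2) stop("multiple PGSE needs N_GP >= 2")
  if (T_M_ms < 0) stop("mixing time must be >= 0")
  g <- G * 1e-3
  eps <- if (is.finite(S_R)) g / S_R * 1e3 else 0
  if (eps >= delta_ms) stop("ramp time G/S_R must be shorter than delta")
  block <- Delta_ms + delta_ms + eps
  comps <- list()
  rf <- numeric(N_GP)
  busy <- list()
  for (k in seq_len(N_GP)) {
    o <- (k - 1) * (block + T_M_ms)
    comps <- c(comps, trap_lobe(o, delta_ms, eps, g),
               trap_lobe(o + Delta_ms, delta_ms, eps, -g))
    rf[k] <- o + (delta_ms + eps + Delta_ms) / 2
    busy <- c(busy, list(c(o, o + delta_ms + eps),
                         c(o + Delta_ms, o + block)))
  }
  end <- (N_GP - 1) * (block + T_M_ms) + block
  if (is.null(TE_ms)) TE_ms <- end
  if (end > TE_ms + 1e-9) stop("timing overflow beyond TE")
  for (r in rf) check_rf_window(r, busy)
  waveform_from_components(comps, ts_us, TE_ms, rf, "multi-PGSE", g,
                           orientation,
                           list(G = G, S_R = S_R, delta_ms = delta_ms,
                                Delta_ms = Delta_ms, T_M_ms = T_M_ms,
                                N_GP = N_GP))
}

#' Stimulated-echo family effective waveforms
#'
#' Covers STE, bipolar STE, multiple STE and bipolar double STE. During the
#' stimulated-echo storage interval (`T_M_ms`) the magnetization is
#' longitudinal and the effective diffusion gradient is zero, so the
#' effective waveform of an STE block equals a PGSE block with lobe
#' separation `Delta + T_M`. In the bipolar variants each `delta` encode is
#' split into two `delta/2` sub-lobes of opposite physical polarity with a
#' refocusing pulse between them; their effective waveform is the contiguous
#' monopolar lobe, so bipolar and monopolar variants match at equal
#' `(G, delta, Delta)`.
#'
#' @inheritParams build_multiple_pgse
#' @param family one of `"STE"`, `"bipolar-STE"`, `"multi-STE"`,
#'   `"bipolar-double-STE"`
#' @param T_M_ms storage/mixing time (ms)
#' @return a `gradient_waveform`
#' @export
build_ste_family <- function(family = c("STE", "bipolar-STE", "multi-STE",
                                        "bipolar-double-STE"),
                             G, delta_ms, Delta_ms, T_M_ms = 0, N_GP = 2,
                             ts_us = 10, S_R = Inf, TE_ms = NULL,
                             orientation = c(1, 0, 0)) {
  family <- match.arg(family)
  wf <- if (family %in% c("STE", "bipolar-STE")) {
    build_pgse(G, delta_ms, Delta_ms + T_M_ms, ts_us, S_R, TE_ms, orientation)
  } else {
    build_multiple_pgse(G, delta_ms, Delta_ms,
                        T_M_ms = if (family == "bipolar-double-STE") T_M_ms else T_M_ms,
                        N_GP = if (family == "bipolar-double-STE") 2 else N_GP,
                        ts_us = ts_us, S_R = S_R, TE_ms = TE_ms,
                        orientation = orientation)
  }
  wf$family <- family
  wf$params$T_M_ms <- T_M_ms
  wf
}

#' Twice-refocused spin-echo (TRSE) effective waveform
#'
#' Four contiguous lobes with refocusing pulses after the first and third, so
#' the effective lobe signs are `+ - - +`. The echo condition requires
#' `d1 - d2 - d3 + d4 = 0`; timings violating it are rejected.
#'
#' @inheritParams build_pgse
#' @param d1_ms,d2_ms,d3_ms,d4_ms the four lobe durations (ms)
#' @return a `gradient_waveform`
#' @export
build_trse <- function(G, d1_ms, d2_ms, d3_ms, d4_ms, ts_us = 10, S_R = Inf,
                       TE_ms = NULL, orientation = c(1, 0, 0)) {
  g <- G * 1e-3
  eps <- if (is.finite(S_R)) g / S_R * 1e3 else 0
  if (abs(d1_ms - d2_ms - d3_ms + d4_ms) > 1e-9)
    stop("lobe durations violate the echo condition (d1 - d2 - d3 + d4 != 0)")
  if (eps >= min(d1_ms, d2_ms, d3_ms, d4_ms))
    stop("ramp time G/S_R must be shorter than every lobe")
  t1 <- 0
  t2 <- t1 + d1_ms + eps
  t3 <- t2 + d2_ms + eps
  t4 <- t3 + d3_ms + eps
  end <- t4 + d4_ms + eps
  comps <- c(trap_lobe(t1, d1_ms, eps, g), trap_lobe(t2, d2_ms, eps, -g),
             trap_lobe(t3, d3_ms, eps, -g), trap_lobe(t4, d4_ms, eps, g))
  if (is.null(TE_ms)) TE_ms <- end
  if (end > TE_ms + 1e-9) stop("timing overflow beyond TE")
  waveform_from_components(comps, ts_us, TE_ms, c(t2 - eps / 2, t4 - eps / 2),
                           "TRSE", g, orientation,
                           list(G = G, S_R = S_R,
                                d_ms = c(d1_ms, d2_ms, d3_ms, d4_ms)))
}

#' Oscillating-gradient spin-echo (OGSE) effective waveform
#'
#' One oscillating lobe of `N_GO` whole periods on each side of a refocusing
#' pulse (the second lobe effective-sign-flipped). Shapes: `sine`
#' (`G sin(2 pi t / T)`), `cosine` (`G cos(2 pi t / T)`), and `double_sine`
#' (two sine cycles per period `T`, i.e. `G sin(4 pi t / T)`).
#'
#' @inheritParams build_pgse
#' @param T_ms oscillation period (ms); frequency `f = 1/T`
#' @param N_GO whole oscillation count per lobe (integer >= 1)
#' @param shape `"sine"`, `"cosine"`, or `"double_sine"`
#' @param Delta_ms separation between lobe starts (ms); defaults to one lobe
#'   duration plus one sampling step
#' @return a `gradient_waveform`
#' @export
build_ogse <- function(G, T_ms, N_GO, shape = c("cosine", "sine", "double_sine"),
                       ts_us = 10, Delta_ms = NULL, TE_ms = NULL,
                       orientation = c(1, 0, 0)) {
  shape <- match.arg(shape)
  if (N_GO < 1 || abs(N_GO - round(N_GO)) > 1e-9)
    stop("N_GO must be a whole number of oscillations (>= 1)")
  N_GO <- round(N_GO)
  g <- G * 1e-3
  tau <- N_GO * T_ms
  if (is.null(Delta_ms)) Delta_ms <- tau + ts_us * 1e-3
  if (Delta_ms < tau) stop("lobes overlap: Delta < lobe duration")
  mk <- function(t0, sgn) {
    Tp <- if (shape == "double_sine") T_ms / 2 else T_ms
    f <- switch(shape, sine = comp_sin, double_sine = comp_sin, cosine = comp_cos)
    f(t0, t0 + tau, sgn * g, Tp)
  }
  comps <- list(mk(0, +1), mk(Delta_ms, -1))
  end <- Delta_ms + tau
  if (is.null(TE_ms)) TE_ms <- end
  if (end > TE_ms + 1e-9) stop("timing overflow beyond TE")
  rf <- (tau + Delta_ms) / 2
  check_rf_window(rf, list(c(0, tau), c(Delta_ms, end)))
  waveform_from_components(comps, ts_us, TE_ms, rf, "OGSE", g, orientation,
                           list(G = G, T_ms = T_ms, f_kHz = 1 / T_ms,
                                N_GO = N_GO, shape = shape,
                                Delta_ms = Delta_ms))
}

#' Rotate or rescale a waveform
#'
#' `rotate_waveform` keeps the timing and changes the gradient orientation;
#' `scale_waveform` multiplies the gradient amplitude by `factor` (used for
#' amplitude sweeps at fixed timing, where the spin phase scales linearly).
#'
#' @param wf a `gradient_waveform`
#' @param orientation new gradient direction
#' @return a `gradient_waveform`
#' @export
rotate_waveform <- function(wf, orientation) {
  wf$orientation <- orientation / sqrt(sum(orientation^2))
  wf
}

#' @rdname rotate_waveform
#' @param factor amplitude scale factor
#' @export
scale_waveform <- function(wf, factor) {
  wf$shape <- wf$shape * factor
  wf$amplitude <- wf$amplitude * factor
  if (!is.null(wf$params$G)) wf$params$G <- wf$params$G * factor
  wf
}

#' Diffusion sensitization (b-value) of a waveform
#'
#' Numerical quadrature of `b = int_0^TE |k(t)|^2 dt` with
#' `k(t) = gamma int_0^t G_eff dt'` on the waveform's sampling grid. Errors
#' if the waveform is unbalanced (nonzero zeroth gradient moment).
#'
#' @param wf a `gradient_waveform`
#' @return b-value in s/mm^2
#' @export
compute_bvalue <- function(wf) {
  ts_s <- wf$ts_us * 1e-6
  cg <- cumsum(wf$shape)
  m0 <- cg[length(cg)] * ts_s
  scale_ref <- max(abs(wf$shape)) * wf$te_ms * 1e-3
  if (scale_ref > 0 && abs(m0) > 1e-9 * scale_ref)
    stop("unbalanced waveform: nonzero zeroth gradient moment")
  k_mid <- GAMMA * ts_s * (cg - wf$shape / 2)   # rad/m at step midpoints
  sum(k_mid^2) * ts_s * 1e-6                     # s/m^2 -> s/mm^2
}

#' q-value of a narrow-pulse sequence
#'
#' `q = gamma delta G / (2 pi)` in cm^-1. For a double PGSE (`N_GP = 2`) with
#' `effective = TRUE` the value is doubled, matching the convention of
#' plotting double-PGSE decays against `2q`.
#'
#' @param wf a `gradient_waveform` from [build_pgse()] or
#'   [build_multiple_pgse()]
#' @param effective double the value for a double PGSE
#' @return q in cm^-1
#' @export
compute_q <- function(wf, effective = FALSE) {
  p <- wf$params
  if (is.null(p$delta_ms)) stop("q is defined for pulsed (PGSE-family) sequences")
  q <- GAMMA * (p$delta_ms * 1e-3) * (p$G * 1e-3) / (2 * pi) / 100
  if (effective && identical(wf$family, "multi-PGSE") && !is.null(p$N_GP))
    q <- q * ifelse(p$N_GP == 2, 2, 1)
  q
}

#' Export an acquisition scheme as FSL-style bval/bvec files
#'
#' @param waveforms list of `gradient_waveform` objects
#' @param prefix output path prefix (writes `<prefix>.bval`, `<prefix>.bvec`)
#' @return the prefix, invisibly
#' @export
write_scheme <- function(waveforms, prefix) {
  bvals <- vapply(waveforms, compute_bvalue, 0)
  bvecs <- vapply(waveforms, function(w) w$orientation, numeric(3))
  writeLines(paste(signif(bvals, 8), collapse = " "), paste0(prefix, ".bval"))
  writeLines(apply(bvecs, 1, paste, collapse = " "), paste0(prefix, ".bvec"))
  invisible(prefix)
}

#' Read a plain-text unit-vector orientation set
#'
#' One direction per row, three whitespace-separated components.
#'
#' @param path text file path
#' @return n x 3 matrix of unit vectors
#' @export
read_orientations <- function(path) {
  m <- as.matrix(read.table(path))
  colnames(m) <- NULL
  m / sqrt(rowSums(m^2))
}
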