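#' Diffusion tensor fit
#'
#' Linear least-squares fit of the log signal model
#' `log(S/S0) = -b g' D g` over the acquisition scheme, followed by
#' eigen-decomposition. The apparent diffusion coefficient is reported as
#' the mean diffusivity (trace/3) and the fractional anisotropy from the
#' eigenvalues (negative eigenvalues are clamped to zero for the scalar
#' maps). Needs at least six non-collinear orientations plus the b = 0
#' reference.
#'
#' @param E normalized attenuations `S/S0` (one per scheme entry)
#' @param bvals b-values (s/mm^2)
#' @param bvecs n x 3 gradient orientations
#' @return a `tensor_fit` with elements `tensor` (3 x 3, mm^2/s),
#'   `eigenvalues`, `adc`, `fa`
#' @export
fit_diffusion_tensor <- function(E, bvals, bvecs) {
  bvecs <- matrix(as.numeric(bvecs), ncol = 3)
  stopifnot(length(E) == length(bvals), nrow(bvecs) == length(bvals))
  ok <- E > 0 & bvals > 0
  y <- -log(E[ok])
  g <- bvecs[ok, , drop = FALSE]
  b <- bvals[ok]
  X <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3]) * b
  if (qr(X)$rank < 6)
    stop("rank-deficient design: need >= 6 non-collinear orientations")
  beta <- qr.coef(qr(X), y)
  Dt <- matrix(c(beta[1], beta[4], beta[5],
                 beta[4], beta[2], beta[6],
                 beta[5], beta[6], beta[3]), 3, 3)
  ev <- eigen(Dt, symmetric = TRUE)$values
  evc <- pmax(ev, 0)
  md <- mean(evc)
  fa <- if (sum(evc^2) > 0)
    sqrt(3 / 2) * sqrt(sum((evc - md)^2) / sum(evc^2)) else 0
  structure(list(tensor = Dt, eigenvalues = ev, adc = md, fa = fa),
            class = "tensor_fit")
}

#' @export
print.tensor_fit <- function(x, ...) {
  cat(sprintf("tensor_fit: ADC %.4g mm^2/s, FA %.3f, eigenvalues %s (mm^2/s)\n",
              x$adc, x$fa, paste(signif(x$eigenvalues, 4), collapse = ", ")))
  invisible(x)
}

#' @export
coef.tensor_fit <- function(object, ...) {
  c(adc = object$adc, fa = object$fa,
    l1 = object$eigenvalues[1], l2 = object$eigenvalues[2],
    l3 = object$eigenvalues[3])
}

biexp_start <- function(b, E) {
  # two-segment log-linear split: tail -> slow pool, residual head -> fast
  tail_ix <- b >= max(b) * 0.55 & E > 0
  if (sum(tail_ix) < 2) tail_ix <- rank(-b) <= 3 & E > 0
  ft <- lm(log(E[tail_ix]) ~ b[tail_ix])
  Ds <- max(0, -coef(ft)[2])
  Fs <- min(1.1, exp(coef(ft)[1]))
  resid_head <- E - Fs * exp(-b * Ds)
  head_ix <- b <= max(b) * 0.3 & resid_head > 1e-8
  Df <- if (sum(head_ix) >= 2) {
    fh <- lm(log(resid_head[head_ix]) ~ b[head_ix])
    max(Ds * 2, -coef(fh)[2])
  } else max(Ds * 10, 1e-3)
  Ff <- max(0.05, min(1.1, 1 - Fs))
  list(Ff = Ff, Df = Df, Fs = Fs, Ds = Ds)
}

#' Biexponential fit of diffusion signal decay
#'
#' Bounded nonlinear least squares of
#' `S/S0 = F_f exp(-b D_f) + F_s exp(-b D_s)` per measurement axis,
#' initialized from a two-segment log-linear split. The pool fractions are
#' bounded to \[0, 1.2\] but not constrained to sum to one, and
#' `D_f >= D_s >= 0` is enforced by ordering after the fit. When several
#' axes are supplied the parameter mean and standard deviation across axes
#' are reported.
#'
#' @param E normalized attenuations: a vector or an `n_b x n_axes` matrix
#' @param bvals b-values (s/mm^2), increasing, including 0
#' @return a `biexp_fit` with `per_axis` (data frame of `F_f`, `D_f`, `F_s`,
#'   `D_s` per axis), `mean`, `sd`
#' @export
fit_biexponential <- function(E, bvals) {
  E <- as.matrix(E)
  stopifnot(nrow(E) == length(bvals))
  fits <- lapply(seq_len(ncol(E)), function(j) {
    y <- E[, j]
    st <- biexp_start(bvals, y)
    dat <- data.frame(b = bvals, y = y)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ Ff * exp(-b * Df) + Fs * exp(-b * Ds), data = dat,
                        start = st,
                        lower = c(Ff = 0, Df = 0, Fs = 0, Ds = 0),
                        upper = c(Ff = 1.2, Df = Inf, Fs = 1.2, Ds = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(F_f = NA, D_f = NA, F_s = NA, D_s = NA,
                        rss = NA, converged = FALSE))
    p <- coef(fit)
    if (p["Df"] < p["Ds"])   # enforce fast/slow ordering
      p <- c(Ff = unname(p["Fs"]), Df = unname(p["Ds"]),
             Fs = unname(p["Ff"]), Ds = unname(p["Df"]))
    data.frame(F_f = unname(p["Ff"]), D_f = unname(p["Df"]),
               F_s = unname(p["Fs"]), D_s = unname(p["Ds"]),
               rss = sum(residuals(fit)^2), converged = TRUE)
  })
  per_axis <- do.call(rbind, fits)
  cn <- colnames(E)
  rownames(per_axis) <- if (!is.null(cn) && !anyDuplicated(cn)) cn else
    paste0("axis", seq_len(ncol(E)))
  pars <- per_axis[, c("F_f", "D_f", "F_s", "D_s"), drop = FALSE]
  structure(list(per_axis = per_axis,
                 mean = colMeans(pars),
                 sd = apply(pars, 2, sd)),
            class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat("biexp_fit (diffusivities in 1e-3 mm^2/s):\n")
  m <- x$mean; s <- x$sd
  cat(sprintf("  F_f = %.4f +/- %.4f   D_f = %.4f +/- %.4f\n",
              m["F_f"], s["F_f"], 1e3 * m["D_f"], 1e3 * s["D_f"]))
  cat(sprintf("  F_s = %.4f +/- %.4f   D_s = %.4f +/- %.4f\n",
              m["F_s"], s["F_s"], 1e3 * m["D_s"], 1e3 * s["D_s"]))
  if (!all(x$per_axis$converged)) cat("  warning: some axes did not converge\n")
  invisible(x)
}

#' @export
coef.biexp_fit <- function(object, ...) object$mean

#' Detect the first diffusion diffraction trough
#'
#' The first strict local minimum of the raw sampled attenuation profile
#' `E(q)` (`E[k-1] > E[k] < E[k+1]`), without smoothing or interpolation.
#'
#' @param q sampled q-values (cm^-1), strictly increasing
#' @param E normalized attenuation at each q
#' @return list with `q_star`, `index`, `E_min`, or `NULL` when the profile
#'   has no interior local minimum (with a message)
#' @export
detect_diffraction_trough <- function(q, E) {
  stopifnot(length(q) == length(E), length(q) >= 5, !is.unsorted(q, strictly = TRUE))
  n <- length(E)
  for (k in 2:(n - 1)) {
    if (E[k - 1] > E[k] && E[k] < E[k + 1])
      return(list(q_star = q[k], index = k, E_min = E[k]))
  }
  message("no diffraction trough: profile has no interior local minimum")
  NULL
}

#' Pore diameter from the diffraction trough (Callaghan relation)
#'
#' For diffusion restricted in a cylindrical pore the first diffraction
#' trough at `q*` (cm^-1) corresponds to a diameter `d = 1.22e4 / q*` (um).
#'
#' @param q_star trough position (cm^-1), positive
#' @return estimated diameter (um)
#' @export
estimate_diameter_callaghan <- function(q_star) {
  if (any(q_star <= 0)) stop("q* must be positive")
  1.22e4 / q_star
}

#' Write a table of fit results as TSV
#'
#' @param df a data frame (e.g. a per-radius parameter table)
#' @param path output path
#' @return the path, invisibly
#' @export
write_fit_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
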