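#' Accumulate the spin phase of recorded trajectories
#'
#' Discrete phase sum over the walk time base:
#' `phi = gamma * sum_i G_eff(t_i) . r(t_i) * t_s`, where the effective
#' gradient already carries the refocusing-pulse sign flips. This is the
#' offline counterpart of the online accumulation in [run_walk()]; it
#' requires a trajectory recorded at every step (`record_stride = 1`)
#' covering the waveform duration.
#'
#' @param trajectory either an `n_steps x 3` matrix (one particle) or an
#'   `n_particles x 3 x n_steps` array of positions (um)
#' @param wf a `gradient_waveform` on the same time base
#' @return accumulated phase(s) in radians
#' @export
accumulate_phase <- function(trajectory, wf) {
  n <- wf$n_steps
  gain <- GAMMA * wf$ts_us * 1e-12   # (T/m um s) -> rad
  if (is.matrix(trajectory)) {
    if (nrow(trajectory) < n)
      stop("trajectory does not cover the waveform duration")
    proj <- trajectory[seq_len(n), , drop = FALSE] %*% wf$orientation
    sum(wf$shape * proj) * gain
  } else {
    stopifnot(length(dim(trajectory)) == 3)
    if (dim(trajectory)[3] < n)
      stop("trajectory does not cover the waveform duration")
    np <- dim(trajectory)[1]
    acc <- numeric(np)
    for (i in seq_len(n)) {
      g <- wf$shape[i]
      if (g != 0) acc <- acc + g * (trajectory[, , i] %*% wf$orientation)
    }
    as.numeric(acc) * gain
  }
}

#' Segregate walkers into fast and slow diffusion pools
#'
#' Walkers whose fraction of residence time within the polar membrane layer
#' reaches `threshold` form the slow pool; the rest form the fast pool. The
#' two sets always partition all walkers.
#'
#' @param walk a [run_walk()] result (or a numeric residence-fraction vector)
#' @param threshold residence fraction in \[0, 1\]
#' @return list with integer index vectors `fast` and `slow`
#' @export
segregate_fast_slow <- function(walk, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  res <- if (is.numeric(walk)) walk else walk$polar_residence
  slow <- which(res >= threshold)
  list(fast = setdiff(seq_along(res), slow), slow = slow)
}

#' Voxel grid specification
#'
#' Half-open voxels `[lo, lo + size)` tiling a field of view.
#'
#' @param dim integer length-3 voxel counts
#' @param size voxel edge lengths (um), length 1 or 3
#' @param origin field-of-view origin (um)
#' @return a `voxel_grid` list
#' @export
voxel_grid <- function(dim, size, origin = c(0, 0, 0)) {
  dim <- as.integer(rep(dim, length.out = 3))
  size <- rep(size, length.out = 3)
  structure(list(dim = dim, size = size, origin = as.numeric(origin)),
            class = "voxel_grid")
}

voxel_index <- function(vg, positions) {
  ix <- floor(sweep(sweep(positions, 2, vg$origin, `-`), 2, vg$size, `/`))
  ok <- ix[, 1] >= 0 & ix[, 1] < vg$dim[1] &
        ix[, 2] >= 0 & ix[, 2] < vg$dim[2] &
        ix[, 3] >= 0 & ix[, 3] < vg$dim[3]
  idx <- ix[, 1] + vg$dim[1] * (ix[, 2] + vg$dim[2] * ix[, 3]) + 1
  idx[!ok] <- NA
  idx
}

#' Diffusion-weighted voxel signal by phase integration
#'
#' `S(v) = | sum_{p in v} exp(-i phi_p) + eta |` where `eta` is complex
#' Gaussian noise with independent zero-mean channels of standard deviation
#' `sigma`. The unweighted signal `S0(v)` is the walker count at TE with the
#' same noise model applied independently. Voxel membership uses the particle
#' position exactly at TE.
#'
#' @param phases accumulated phases (rad), one per walker
#' @param positions walker positions at TE (n x 3, um)
#' @param vg a [voxel_grid()]
#' @param sigma noise standard deviation per channel (signal units; 0 = none)
#' @param seed RNG seed for the noise draws
#' @return list with arrays `S`, `S0`, `counts` of dimension `vg$dim`
#' @export
voxel_signal <- function(phases, positions, vg, sigma = 0, seed = 1) {
  if (sigma < 0) stop("sigma must be >= 0")
  stopifnot(length(phases) == nrow(positions))
  idx <- voxel_index(vg, positions)
  nv <- prod(vg$dim)
  keep <- !is.na(idx)
  re <- rowsum(cos(phases[keep]), idx[keep])
  im <- rowsum(-sin(phases[keep]), idx[keep])
  cnt <- rowsum(rep(1, sum(keep)), idx[keep])
  S <- S0 <- counts <- numeric(nv)
  at <- as.integer(rownames(re))
  counts[at] <- cnt
  S_re <- S_im <- S0_re <- S0_im <- numeric(nv)
  S_re[at] <- re
  S_im[at] <- im
  S0_re[at] <- cnt
  if (sigma > 0) {
    noise <- with_seed(seed, matrix(rnorm(4 * nv, 0, sigma), nv, 4))
    S_re <- S_re + noise[, 1]; S_im <- S_im + noise[, 2]
    S0_re <- S0_re + noise[, 3]; S0_im <- S0_im + noise[, 4]
  }
  dim(S) <- dim(S0) <- dim(counts) <- vg$dim
  S[] <- sqrt(S_re^2 + S_im^2)
  S0[] <- sqrt(S0_re^2 + S0_im^2)
  counts[] <- counts
  list(S = S, S0 = S0, counts = counts)
}

#' Synthesize a diffusion-weighted image volume
#'
#' Integrates per-voxel signals for a set of gradient waveforms (one per
#' gradient orientation/amplitude) from a walk that accumulated their
#' phases, attaching the numerically computed b-values and orientations.
#' The noise seed is independent of the walk seed, so an acquisition can be
#' re-noised without re-running the walk. Deterministic given the seed.
#'
#' @param walk a [run_walk()] result with phases for the waveform set
#' @param vg a [voxel_grid()]
#' @param sigma complex-noise standard deviation per channel
#' @param seed noise RNG seed
#' @return a `synthetic_image`: `S` (array, `c(vg$dim, n_waveforms)`), `S0`
#'   (array `vg$dim`), `bvals`, `bvecs`, `sigma`, `vg`
#' @export
synthesize_image <- function(walk, vg, sigma = 0, seed = 1) {
  if (is.null(walk$phases)) stop("walk carries no accumulated phases")
  nw <- ncol(walk$phases)
  S <- array(0, c(vg$dim, nw))
  S0 <- NULL
  for (w in seq_len(nw)) {
    vs <- voxel_signal(walk$phases[, w], walk$positions, vg, sigma,
                       seed = seed + w)
    S[, , , w] <- vs$S
    if (w == 1) S0 <- vs$S0
  }
  structure(list(S = S, S0 = S0,
                 bvals = vapply(walk$waveforms, compute_bvalue, 0),
                 bvecs = t(vapply(walk$waveforms, function(x) x$orientation,
                                  numeric(3))),
                 sigma = sigma, vg = vg),
            class = "synthetic_image")
}

#' @export
print.synthetic_image <- function(x, ...) {
  cat(sprintf("synthetic_image: %d x %d x %d voxels, %d volumes, b in [%.3g, %.3g] s/mm^2, sigma = %g\n",
              x$vg$dim[1], x$vg$dim[2], x$vg$dim[3], length(x$bvals),
              min(x$bvals), max(x$bvals), x$sigma))
  invisible(x)
}

#' Write a synthetic image as NIfTI-1
#'
#' Voxel dimensions are recorded in the header in millimetres
#' (micrometre sizes scaled by 1e-3).
#'
#' @param image a [synthesize_image()] result
#' @param path output file path (`.nii` / `.nii.gz`)
#' @return the path, invisibly
#' @export
write_image_nifti <- function(image, path) {
  img <- RNifti::asNifti(image$S, pixdim = c(image$vg$size * 1e-3, 1))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Whole-box signal attenuation
#'
#' Treats the entire scene as a single voxel and returns the noise-free
#' normalized attenuation `|sum exp(-i phi)| / N_p` for each waveform,
#' optionally restricted to a subset of walkers (e.g. a diffusion pool).
#'
#' @param walk a [run_walk()] result with phases
#' @param subset optional integer index vector of walkers
#' @return numeric vector of attenuations, one per waveform
#' @export
bulk_attenuation <- function(walk, subset = NULL) {
  ph <- walk$phases
  if (is.null(ph)) stop("walk carries no accumulated phases")
  if (!is.null(subset)) ph <- ph[subset, , drop = FALSE]
  apply(ph, 2, function(p) Mod(sum(exp(-1i * p))) / length(p))
}
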