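#' Elementary step length of a random walker
#'
#' Three-dimensional Einstein relation: the root-mean-squared displacement
#' per time step is `r = sqrt(6 D t_s)`. With `D` in mm^2/s and `t_s` in
#' microseconds the result is in micrometres (1 mm^2/s = 1 um^2/us).
#'
#' @param D diffusivity (mm^2/s)
#' @param ts_us time step (us)
#' @return step length (um)
#' @export
step_length <- function(D, ts_us) {
  if (any(D < 0)) stop("diffusivity must be >= 0")
  if (any(ts_us <= 0)) stop("time step must be positive")
  sqrt(6 * D * ts_us)
}

#' Walk parameters
#'
#' @param n_particles number of walkers
#' @param n_steps number of iterations; simulated duration is
#'   `n_steps * ts_us`
#' @param ts_us time step (us)
#' @param D global diffusivity (mm^2/s)
#' @param seed master RNG seed (spawns one independent stream per particle)
#' @param record_stride record walker positions every this many steps
#'   (0 = record only final positions)
#' @return a `walk_params` list
#' @export
walk_params <- function(n_particles, n_steps, ts_us, D, seed = 1,
                        record_stride = 0) {
  stopifnot(n_particles >= 1, n_steps >= 1, ts_us > 0, D >= 0)
  structure(list(n_particles = as.integer(n_particles),
                 n_steps = as.integer(n_steps), ts_us = ts_us, D = D,
                 seed = seed, record_stride = as.integer(record_stride)),
            class = "walk_params")
}

#' Particle initialization specification
#'
#' Three modes: `"fractions"` places `round(f_i * N_p)` walkers inside
#' membranes and the rest outside (rejection sampling); `"uniform"` scatters
#' walkers uniformly over the box (the intracellular fraction is then set by
#' the cellular volume); `"region"` confines the start positions to a box
#' (or a single point).
#'
#' @param mode `"uniform"`, `"fractions"`, or `"region"`
#' @param f_i intracellular fraction (mode `"fractions"`)
#' @param region `list(lo =, hi =)` box corners (um), or a length-3 point
#' @return a `particle_init` list
#' @export
particle_init <- function(mode = c("uniform", "fractions", "region"),
                          f_i = NULL, region = NULL) {
  mode <- match.arg(mode)
  if (mode == "fractions") {
    if (is.null(f_i) || f_i < 0 || f_i > 1) stop("fractions mode needs f_i in [0, 1]")
  }
  if (mode == "region" && is.null(region)) stop("region mode needs a region")
  structure(list(mode = mode, f_i = f_i, region = region),
            class = "particle_init")
}

with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Initialize walker positions and compartment labels
#'
#' @param grid a [build_subvolume_grid()] result
#' @param init a [particle_init()]
#' @param n number of walkers
#' @param seed RNG seed
#' @return list with `positions` (n x 3, um) and `labels` (integer; 0 =
#'   extracellular, otherwise the 1-based membrane-instance index)
#' @export
initialize_particles <- function(grid, init, n, seed = 1) {
  stopifnot(inherits(grid, "subvolume_grid"), inherits(init, "particle_init"))
  b <- grid$scene$bounds
  unif_box <- function(k, lo = c(0, 0, 0), hi = b)
    cbind(runif(k, lo[1], hi[1]), runif(k, lo[2], hi[2]), runif(k, lo[3], hi[3]))
  with_seed(seed, {
    if (init$mode == "uniform") {
      pos <- unif_box(n)
      lab <- locate_points(grid, pos)
    } else if (init$mode == "region") {
      r <- init$region
      if (is.numeric(r) && length(r) == 3)
        pos <- matrix(rep(as.numeric(r), each = n), n, 3)
      else
        pos <- unif_box(n, r$lo, r$hi)
      lab <- locate_points(grid, pos)
    } else {
      if (length(grid$scene$membranes) == 0 && init$f_i > 0)
        stop("f_i > 0 requested but the scene has no closed membranes")
      n_in <- round(init$f_i * n)
      pos_in <- matrix(0, 0, 3); lab_in <- integer(0)
      pos_out <- matrix(0, 0, 3)
      guard <- 0
      while ((nrow(pos_in) < n_in || nrow(pos_out) < n - n_in) && guard < 10000) {
        guard <- guard + 1
        cand <- unif_box(max(1000, n))
        lc <- locate_points(grid, cand)
        inside <- !is.na(lc)
        if (nrow(pos_in) < n_in) {
          take <- which(inside)[seq_len(min(sum(inside), n_in - nrow(pos_in)))]
          pos_in <- rbind(pos_in, cand[take, , drop = FALSE])
          lab_in <- c(lab_in, lc[take])
        }
        if (nrow(pos_out) < n - n_in) {
          take <- which(!inside)[seq_len(min(sum(!inside), n - n_in - nrow(pos_out)))]
          pos_out <- rbind(pos_out, cand[take, , drop = FALSE])
        }
      }
      if (nrow(pos_in) < n_in || nrow(pos_out) < n - n_in)
        stop("rejection sampling failed to reach the requested fractions")
      pos <- rbind(pos_in, pos_out)
      lab <- c(lab_in, rep(NA_integer_, n - n_in))
    }
    list(positions = pos, labels = ifelse(is.na(lab), 0L, as.integer(lab)))
  })
}

#' Run the random-walk Monte Carlo
#'
#' Each iteration every walker draws a direction uniformly from the lookup
#' table and attempts a step of length `sqrt(6 D_local t_s)`. Segment tracing
#' handles the interactions: at each membrane encounter a Bernoulli draw
#' against the membrane permeability decides transmission (straight
#' continuation, compartment label flip) versus specular reflection, with the
#' remaining path length conserved; scene-boundary hits reflect or wrap
#' according to the scene's boundary mode. When a polar membrane layer is
#' configured, the local diffusivity is `D_slow` within distance `h` of any
#' membrane surface and the global `D` otherwise, re-evaluated every step,
#' and the per-walker residence fraction is accumulated. More than 100
#' interactions in a single step abort that step in place (pathological
#' geometry guard; the count is reported).
#'
#' Waveform phases are accumulated online: for each supplied waveform,
#' `phi_p = gamma * sum_i G_eff(t_i) . r_p(t_i) * t_s` with positions taken
#' at the end of each step. Under periodic boundaries the phases and the
#' recorded trajectory use the continuous (unwrapped) positions, while the
#' returned final `positions` are the in-box (wrapped) coordinates used for
#' voxel binning. Results are fully reproducible from the seed and
#' independent of the grid dimensions.
#'
#' @param grid a [build_subvolume_grid()] result
#' @param params a [walk_params()]
#' @param init list with `positions` and `labels` (see
#'   [initialize_particles()])
#' @param directions an n x 3 direction table (see
#'   [generate_direction_table()])
#' @param waveforms optional list of `gradient_waveform` objects whose phases
#'   are accumulated during the walk (their `ts_us` must match the walk's and
#'   their step count must not exceed `n_steps`)
#' @return a `walk_result`: `positions` (final, n x 3), `phases`
#'   (n x n_waveforms, rad), `labels`, `polar_residence`, `trajectory`
#'   (n x 3 x n_recorded when `record_stride > 0`), `n_aborted_steps`, plus
#'   the inputs' metadata
#' @export
run_walk <- function(grid, params, init, directions, waveforms = list()) {
  stopifnot(inherits(grid, "subvolume_grid"), inherits(params, "walk_params"))
  directions <- unclass(directions)
  stopifnot(is.matrix(directions), ncol(directions) == 3)
  pos <- init$positions
  stopifnot(nrow(pos) == params$n_particles)
  labels <- init$labels
  if (is.null(labels)) labels <- integer(nrow(pos))
  if (inherits(waveforms, "gradient_waveform")) waveforms <- list(waveforms)
  nw <- length(waveforms)
  if (nw > 0) {
    for (w in waveforms) {
      if (abs(w$ts_us - params$ts_us) > 1e-9)
        stop("waveform time base does not match the walk time step")
      if (w$n_steps > params$n_steps)
        stop("waveform is longer than the walk")
    }
    shapes <- matrix(0, params$n_steps, nw)
    for (j in seq_len(nw)) shapes[seq_len(waveforms[[j]]$n_steps), j] <-
        waveforms[[j]]$shape
    orients <- t(vapply(waveforms, function(w) w$orientation, numeric(3)))
  } else {
    shapes <- matrix(0, params$n_steps, 0)
    orients <- matrix(0, 0, 3)
  }
  res <- cpp_run_walk(grid$ptr, params$D, params$ts_us, params$n_steps,
                      matrix(as.numeric(directions), ncol = 3), pos,
                      as.integer(labels), shapes, orients,
                      params$record_stride, as.numeric(params$seed))
  phases <- if (nw > 0) res$moments[, seq_len(nw), drop = FALSE] *
      (GAMMA * params$ts_us * 1e-12) else NULL
  traj <- NULL
  if (params$record_stride > 0) {
    traj <- aperm(res$trajectory, c(2, 1, 3))   # particle x coord x time
  }
  structure(list(positions = res$final_pos, phases = phases,
                 labels = res$labels, polar_residence = res$polar_residence,
                 trajectory = traj, n_aborted_steps = res$n_aborted_steps,
                 params = params, waveforms = waveforms,
                 start_positions = pos),
            class = "walk_result")
}

#' @export
print.walk_result <- function(x, ...) {
  cat(sprintf("walk_result: %d walkers, %d steps of %g us (%.3g ms), D = %g mm^2/s\n",
              x$params$n_particles, x$params$n_steps, x$params$ts_us,
              x$params$n_steps * x$params$ts_us * 1e-3, x$params$D))
  if (!is.null(x$phases))
    cat(sprintf("  phases accumulated for %d waveform(s)\n", ncol(x$phases)))
  if (x$n_aborted_steps > 0)
    cat(sprintf("  %d step(s) aborted by the interaction guard\n",
                x$n_aborted_steps))
  invisible(x)
}

#' Advance particles by one explicit step
#'
#' Low-level single-step interface used to probe the interaction rules:
#' each particle attempts one step of the given length along the given
#' direction, with full membrane/boundary handling.
#'
#' @param grid a [build_subvolume_grid()] result
#' @param positions n x 3 start positions (um)
#' @param directions n x 3 unit step directions
#' @param lengths step length(s) (um), recycled
#' @param labels compartment labels (0 = extracellular)
#' @param seed RNG seed for the transmission draws
#' @return list with `position`, `direction`, `label`, `n_events`, `aborted`
#' @export
advance_particle <- function(grid, positions, directions, lengths,
                             labels = NULL, seed = 1) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  directions <- matrix(as.numeric(directions), ncol = 3)
  n <- nrow(positions)
  if (is.null(labels)) labels <- integer(n)
  cpp_advance_particles(grid$ptr, positions, as.integer(labels), directions,
                        rep(as.numeric(lengths), length.out = n),
                        as.numeric(seed))
}

#' Mean squared displacement of recorded trajectories
#'
#' @param walk a [run_walk()] result with `record_stride > 0`
#' @return data frame with time (ms), total MSD and per-axis displacement
#'   variances (um^2)
#' @export
trajectory_msd <- function(walk) {
  if (is.null(walk$trajectory)) stop("walk was run without trajectory recording")
  tr <- walk$trajectory
  p0 <- walk$start_positions
  nt <- dim(tr)[3]
  stride_ms <- walk$params$record_stride * walk$params$ts_us * 1e-3
  out <- data.frame(time_ms = seq_len(nt) * stride_ms)
  disp2 <- vapply(seq_len(nt), function(k) {
    d <- tr[, , k] - p0
    c(mean(rowSums(d^2)), colMeans(d^2))
  }, numeric(4))
  out$msd <- disp2[1, ]
  out$var_x <- disp2[2, ]
  out$var_y <- disp2[3, ]
  out$var_z <- disp2[4, ]
  out
}
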