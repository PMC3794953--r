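# Benchmark fixtures: configuration generators that reproduce the study
# conditions of the four benchmark families, plus an end-to-end pipeline
# runner. Fixtures at scale = 1 carry the full-scale parameters; scale < 1
# reduces the walker count (and optionally coarsens the time step), never
# the scene geometry.

#' Uniformly distributed gradient orientations
#'
#' `n` unique orientations from the electrostatic-repulsion optimizer (the
#' independent half of an antipodal set).
#'
#' @param n orientation count
#' @param seed optimizer seed
#' @param iterations optimizer iteration cap
#' @return n x 3 matrix of unit vectors
#' @export
uniform_orientations <- function(n, seed = 7, iterations = 1500) {
  res <- cpp_optimize_directions(as.integer(n), as.integer(iterations),
                                 as.numeric(seed), 1e-10)
  res$directions
}

scaled_np <- function(np, scale, floor_np = 500) max(floor_np, round(np * scale))

#' Benchmark fixture configurations
#'
#' Emits a run configuration holding the scene, walk, sequence and analysis
#' parameters of one of the benchmark families:
#' \describe{
#'   \item{A_grid}{15^3 spheres (R = 5 um, spacing 10 um) in a 150^3 um^3
#'     box; walkers start inside the spheres. Used to exercise the
#'     subvolume-grid acceleration.}
#'   \item{A_fibers}{hexagonal array of 400 impermeable fibers (d = 10 um,
#'     spacing 10.1 um, length 250 um) with a 100-direction PGSE scheme.}
#'   \item{B_msdi}{24 x 24 hexagonal lattice of 19 um impermeable cylinders
#'     at 19.1 um spacing in 460 x 400 x 1000 um^3; single PGSE
#'     (G = 0..1200 mT/m by 10) and double PGSE (0..600 by 5) with
#'     delta/Delta/T_M = 2/200/0 ms, gradients perpendicular to the fibers.}
#'   \item{C_swelling}{ten 100^3 um^3 scenes of 9,200 spheres (R = 2.40 to
#'     2.58 um by 0.02, spacing 5.2 um), D = 1.2e-3 mm^2/s; a constant-D
#'     variant and a biphasic variant with a 40 nm polar layer per side
#'     (D_slow = 0.4e-3 mm^2/s). PGSE shells: 80 directions at
#'     b = 1000 s/mm^2 (delta/Delta = 21/27 ms) and 51 b-values 0..5000
#'     s/mm^2 along x/y/z (delta/Delta = 2/70.5 ms).}
#'   \item{D_hardi}{crossing-fiber phantom with a 200-direction PGSE scheme
#'     at b = 4000 s/mm^2 (G = 40 mT/m, S_R = 200 T/m/s,
#'     delta/Delta/TE = 34.75/40.75/80 ms), synthesized on a single slice of
#'     5 x 5 um^2 in-plane voxels.}
#' }
#'
#' @param name fixture name
#' @param scale walker-count scale factor in (0, 1]
#' @param ts_us optional coarsened time step (us); the step count is
#'   adjusted to preserve the simulated duration
#' @param biphasic for `C_swelling`: use the polar-membrane-layer variant
#' @return a `run_config` list (YAML-serializable)
#' @export
make_fixture <- function(name = c("A_grid", "A_fibers", "B_msdi", "C_swelling",
                                  "D_hardi"),
                         scale = 1, ts_us = NULL, biphasic = FALSE) {
  name <- match.arg(name)
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  cfg <- switch(name,
    A_grid = list(
      scene = list(generator = "cubic_sphere_grid", n = 15, R = 5,
                   spacing = 10, bounds = c(150, 150, 150)),
      walk = list(np = 1e4, n_steps = 1000, ts_us = 10, D = 1e-3,
                  grid = c(50, 50, 50)),
      particles = list(init = "fractions", f_i = 1, table_n = 500),
      analysis = list(kind = "none")),
    A_fibers = list(
      scene = list(generator = "hex_cylinder_lattice", rows = 20, cols = 20,
                   diameter = 10, spacing = 10.1, length = 250),
      walk = list(np = 1e4, n_steps = 7000, ts_us = 10, D = 2e-3,
                  grid = c(50, 50, 50)),
      particles = list(init = "uniform", table_n = 500),
      sequences = list(list(family = "PGSE", G = 40, S_R = 200,
                            delta_ms = 31.7, Delta_ms = 37.7, TE_ms = 70,
                            n_orientations = 100)),
      analysis = list(kind = "dti")),
    B_msdi = list(
      scene = list(generator = "hex_cylinder_lattice", rows = 24, cols = 24,
                   diameter = 19, spacing = 19.1, length = 1000,
                   bounds = c(460, 400, 1000)),
      walk = list(np = 5e5, n_steps = NA, ts_us = 5, D = 2e-3,
                  grid = c(160, 160, 20)),
      particles = list(init = "uniform", table_n = 500),
      sequences = list(
        single = list(family = "PGSE", delta_ms = 2, Delta_ms = 200,
                      S_R = 5000, G_max = 1200, G_step = 10,
                      orientation = c(1, 0, 0)),
        double = list(family = "multi-PGSE", delta_ms = 2, Delta_ms = 200,
                      T_M_ms = 0, N_GP = 2, S_R = 5000, G_max = 600,
                      G_step = 5, orientation = c(1, 0, 0))),
      analysis = list(kind = "diffraction")),
    C_swelling = list(
      scene = list(generator = "hex_sphere_lattice", bounds = c(100, 100, 100),
                   R_values = seq(2.40, 2.58, by = 0.02), spacing = 5.2,
                   n_spheres = 9200, level = 3, boundary = "periodic",
                   biphasic = biphasic,
                   polar = if (biphasic) list(h_um = 0.04, D_slow = 0.4e-3,
                                              D_fast = 1.2e-3) else NULL),
      walk = list(np = 1e6, n_steps = 15500, ts_us = 5, D = 1.2e-3,
                  grid = c(100, 100, 100)),
      particles = list(init = "uniform", table_n = 4000),
      sequences = list(
        dti = list(family = "PGSE", G = 40, S_R = 200, delta_ms = 21,
                   Delta_ms = 27, n_orientations = 80),
        biexp = list(family = "PGSE", delta_ms = 2, Delta_ms = 70.5,
                     S_R = 5000, b_max = 5000, n_b = 51,
                     axes = rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))),
      analysis = list(kind = "swelling", do_dti = TRUE, do_biexp = TRUE)),
    D_hardi = list(
      scene = list(generator = "fiber_configuration", kind = "crossing",
                   diameter = 5),
      walk = list(np = 1e6, n_steps = 8000, ts_us = 10, D = 2e-3,
                  grid = c(150, 150, 50)),
      particles = list(init = "uniform", table_n = 500),
      sequences = list(list(family = "PGSE", G = 40, S_R = 200,
                            delta_ms = 34.75, Delta_ms = 40.75, TE_ms = 80,
                            n_orientations = 200)),
      synthesis = list(voxel_um = c(5, 5, NA), sigma = 0),
      analysis = list(kind = "hardi")))
  cfg$fixture <- name
  cfg$scale <- scale
  duration_us <- if (is.na(cfg$walk$n_steps %||% NA)) NA else
    cfg$walk$n_steps * cfg$walk$ts_us
  cfg$walk$np <- scaled_np(cfg$walk$np, scale)
  if (!is.null(ts_us)) {
    if (!is.na(duration_us))
      cfg$walk$n_steps <- ceiling(duration_us / ts_us)
    cfg$walk$ts_us <- ts_us
  }
  cfg$seeds <- list(walk = 1, init = 2, noise = 3, table = 20130101)
  class(cfg) <- c("run_config", "list")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the scene described by a run configuration
#'
#' @param config a `run_config` (see [make_fixture()])
#' @param R for `C_swelling` configs: the sphere radius to instantiate
#' @return a [scene()]
#' @export
scene_from_config <- function(config, R = NULL) {
  sc <- config$scene
  switch(sc$generator,
    cubic_sphere_grid = make_cubic_sphere_grid(sc$n, sc$R, sc$spacing, sc$bounds),
    hex_cylinder_lattice = make_hexagonal_cylinder_lattice(
      sc$rows, sc$cols, sc$diameter, sc$spacing, sc$length,
      bounds = sc$bounds %||% NULL),
    hex_sphere_lattice = make_hexagonal_sphere_lattice(
      sc$bounds, R %||% sc$R_values[1], sc$spacing, n_spheres = sc$n_spheres,
      level = sc$level %||% 3,
      polar = if (isTRUE(sc$biphasic)) sc$polar else NULL,
      boundary = sc$boundary %||% "reflective"),
    fiber_configuration = make_fiber_configuration(sc$kind, sc$diameter),
    stop("unknown scene generator: ", sc$generator))
}

b_ladder_amplitude <- function(seqspec) {
  # peak gradient (mT/m) of a rectangular-dominated PGSE reaching b_max
  d <- seqspec$delta_ms * 1e-3
  D <- seqspec$Delta_ms * 1e-3
  b_SI <- seqspec$b_max * 1e6
  sqrt(b_SI / (GAMMA^2 * d^2 * (D - d / 3))) * 1e3
}

run_msdi <- function(config, table, progress = FALSE) {
  sc <- scene_from_config(config)
  grid <- build_subvolume_grid(sc, config$walk$grid)
  init <- initialize_particles(grid, particle_init("uniform"),
                               config$walk$np, config$seeds$init)
  sg <- config$sequences$single
  dg <- config$sequences$double
  ts <- config$walk$ts_us
  wf_s <- build_pgse(sg$G_max, sg$delta_ms, sg$Delta_ms, ts, sg$S_R,
                     orientation = sg$orientation)
  wf_d <- build_multiple_pgse(dg$G_max, dg$delta_ms, dg$Delta_ms, dg$T_M_ms,
                              dg$N_GP, ts, dg$S_R,
                              orientation = dg$orientation)
  n_steps <- max(wf_s$n_steps, wf_d$n_steps)
  wp <- walk_params(config$walk$np, n_steps, ts, config$walk$D,
                    seed = config$seeds$walk)
  walk <- run_walk(grid, wp, init, table, list(wf_s, wf_d))
  sweep_E <- function(phi_ref, G_ref, G_values) {
    vapply(G_values, function(G) {
      Mod(sum(exp(-1i * phi_ref * (G / G_ref)))) / length(phi_ref)
    }, 0)
  }
  Gs <- seq(0, sg$G_max, by = sg$G_step)
  Gd <- seq(0, dg$G_max, by = dg$G_step)
  q_s <- GAMMA * (sg$delta_ms * 1e-3) * (Gs * 1e-3) / (2 * pi) / 100
  q_d <- 2 * GAMMA * (dg$delta_ms * 1e-3) * (Gd * 1e-3) / (2 * pi) / 100
  single <- data.frame(G = Gs, q = q_s,
                       E = sweep_E(walk$phases[, 1], sg$G_max, Gs))
  double <- data.frame(G = Gd, q = q_d,
                       E = sweep_E(walk$phases[, 2], dg$G_max, Gd))
  trough <- detect_diffraction_trough(single$q, single$E)
  list(single = single, double = double, trough = trough,
       diameter_um = if (!is.null(trough))
         estimate_diameter_callaghan(trough$q_star) else NA_real_,
       f_i = intracellular_volume_fraction(sc))
}

run_swelling_one <- function(config, R, table) {
  sc <- scene_from_config(config, R = R)
  grid <- build_subvolume_grid(sc, config$walk$grid)
  init <- initialize_particles(grid, particle_init("uniform"),
                               config$walk$np, config$seeds$init)
  ts <- config$walk$ts_us
  an <- config$analysis
  waveforms <- list()
  bx <- config$sequences$biexp
  if (isTRUE(an$do_biexp)) {
    G_ref <- b_ladder_amplitude(bx)
    for (ax in seq_len(nrow(bx$axes)))
      waveforms <- c(waveforms, list(
        build_pgse(G_ref, bx$delta_ms, bx$Delta_ms, ts, bx$S_R,
                   orientation = bx$axes[ax, ])))
  }
  dt <- config$sequences$dti
  dti_dirs <- NULL
  if (isTRUE(an$do_dti)) {
    dti_dirs <- uniform_orientations(dt$n_orientations, seed = 11)
    for (k in seq_len(nrow(dti_dirs)))
      waveforms <- c(waveforms, list(
        build_pgse(dt$G, dt$delta_ms, dt$Delta_ms, ts, dt$S_R,
                   orientation = dti_dirs[k, ])))
  }
  n_steps <- max(vapply(waveforms, function(w) w$n_steps, 0L))
  wp <- walk_params(config$walk$np, n_steps, ts, config$walk$D,
                    seed = config$seeds$walk)
  walk <- run_walk(grid, wp, init, table, waveforms)
  out <- list(R = R, f_i = intracellular_volume_fraction(sc))
  iw <- 0
  if (isTRUE(an$do_biexp)) {
    n_ax <- nrow(bx$axes)
    bv <- seq(0, bx$b_max, length.out = bx$n_b)
    G_ref <- b_ladder_amplitude(bx)
    wf_ref <- waveforms[[1]]
    b_ref <- compute_bvalue(wf_ref)
    Emat <- matrix(0, bx$n_b, n_ax)
    bnum <- b_ref * (bv / bx$b_max)   # b scales with G^2; ladder by amplitude
    fac <- sqrt(bv / bx$b_max)
    for (ax in seq_len(n_ax)) {
      phi <- walk$phases[, iw + ax]
      Emat[, ax] <- vapply(fac, function(f)
        Mod(sum(exp(-1i * phi * f))) / length(phi), 0)
    }
    iw <- iw + n_ax
    out$biexp <- fit_biexponential(Emat, bnum)
    out$attenuation <- data.frame(b = bnum, Emat)
  }
  if (isTRUE(an$do_dti)) {
    nd <- nrow(dti_dirs)
    E <- bulk_attenuation(walk)[iw + seq_len(nd)]
    bv <- vapply(waveforms[iw + seq_len(nd)], compute_bvalue, 0)
    out$dti <- fit_diffusion_tensor(E, bv, dti_dirs)
    out$adc <- out$dti$adc
  }
  out
}

run_swelling <- function(config, table, progress = FALSE) {
  rows <- lapply(config$scene$R_values, function(R) {
    if (progress) message(sprintf("  radius %.2f um", R))
    run_swelling_one(config, R, table)
  })
  summary <- do.call(rbind, lapply(rows, function(r) {
    data.frame(R = r$R, f_i = r$f_i,
               adc = r$adc %||% NA_real_,
               F_f = if (!is.null(r$biexp)) r$biexp$mean["F_f"] else NA_real_,
               D_f = if (!is.null(r$biexp)) r$biexp$mean["D_f"] else NA_real_,
               F_s = if (!is.null(r$biexp)) r$biexp$mean["F_s"] else NA_real_,
               D_s = if (!is.null(r$biexp)) r$biexp$mean["D_s"] else NA_real_)
  }))
  rownames(summary) <- NULL
  list(per_radius = rows, summary = summary)
}

run_hardi <- function(config, table, progress = FALSE) {
  sc <- scene_from_config(config)
  grid <- build_subvolume_grid(sc, config$walk$grid)
  init <- initialize_particles(grid, particle_init("uniform"),
                               config$walk$np, config$seeds$init)
  sq <- config$sequences[[1]]
  ts <- config$walk$ts_us
  dirs <- uniform_orientations(sq$n_orientations, seed = 13)
  waveforms <- lapply(seq_len(nrow(dirs)), function(k)
    build_pgse(sq$G, sq$delta_ms, sq$Delta_ms, ts, sq$S_R, sq$TE_ms,
               orientation = dirs[k, ]))
  wp <- walk_params(config$walk$np,
                    max(vapply(waveforms, function(w) w$n_steps, 0L)),
                    ts, config$walk$D, seed = config$seeds$walk)
  walk <- run_walk(grid, wp, init, table, waveforms)
  vx <- config$synthesis$voxel_um
  vg <- voxel_grid(c(floor(sc$bounds[1] / vx[1]), floor(sc$bounds[2] / vx[2]), 1),
                   c(vx[1], vx[2], sc$bounds[3]))
  img <- synthesize_image(walk, vg, config$synthesis$sigma, config$seeds$noise)
  list(image = img, scheme = list(bvals = img$bvals, bvecs = img$bvecs),
       walk_summary = list(np = wp$n_particles, n_steps = wp$n_steps))
}

run_basic_walk <- function(config, table, progress = FALSE) {
  sc <- scene_from_config(config)
  grid <- build_subvolume_grid(sc, config$walk$grid)
  pi_spec <- if (config$particles$init == "fractions")
    particle_init("fractions", f_i = config$particles$f_i)
  else particle_init("uniform")
  init <- initialize_particles(grid, pi_spec, config$walk$np, config$seeds$init)
  wp <- walk_params(config$walk$np, config$walk$n_steps, config$walk$ts_us,
                    config$walk$D, seed = config$seeds$walk,
                    record_stride = max(1, config$walk$n_steps %/% 50))
  walk <- run_walk(grid, wp, init, table)
  list(walk = walk, msd = trajectory_msd(walk))
}

#' Run a benchmark pipeline end to end
#'
#' Executes walk, signal synthesis and analysis for a fixture configuration
#' and optionally archives the configuration and results.
#'
#' @param config a `run_config` from [make_fixture()]
#' @param outdir optional output directory (written: `config.yaml`,
#'   `results.rds`, TSV summary tables, NIfTI volumes where applicable)
#' @param table optional direction table (defaults to a cached table of the
#'   configured size)
#' @param progress print stage messages
#' @return results list (fixture-dependent)
#' @export
run_pipeline <- function(config, outdir = NULL, table = NULL, progress = FALSE) {
  stopifnot(inherits(config, "run_config") || is.list(config))
  if (is.null(table))
    table <- default_direction_table(config$particles$table_n,
                                     seed = config$seeds$table)
  res <- switch(config$analysis$kind %||% "none",
    diffraction = run_msdi(config, table, progress),
    swelling = run_swelling(config, table, progress),
    hardi = run_hardi(config, table, progress),
    dti = ,
    none = run_basic_walk(config, table, progress))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_config(unclass(rapply(config, function(x)
      if (is.matrix(x)) as.data.frame(x) else x, how = "replace")),
      file.path(outdir, "config.yaml"))
    saveRDS(res, file.path(outdir, "results.rds"))
    if (!is.null(res$summary))
      write_fit_table(res$summary, file.path(outdir, "summary.tsv"))
    if (!is.null(res$single))
      write_fit_table(res$single, file.path(outdir, "profile_single.tsv"))
    if (!is.null(res$image))
      write_image_nifti(res$image, file.path(outdir, "dwi.nii.gz"))
  }
  res
}
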