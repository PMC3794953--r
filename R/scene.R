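#' Membrane: a mesh surface with interaction properties
#'
#' A membrane couples a [triangle_mesh()] to the physics of the walker-
#' membrane encounter: a transmission probability (`permeability`), an
#' optional polar membrane layer (a slow-diffusion film of thickness `h_um`
#' on each side of the surface), and an optional morphological evolution
#' schedule. A membrane may be instanced: `instances` is a matrix of
#' translations, one row per copy of the template mesh, which keeps lattice
#' scenes with thousands of identical cells cheap to store.
#'
#' @param mesh a [triangle_mesh()] template
#' @param permeability transmission probability per encounter, in \[0, 1\]
#' @param polar optional `list(h_um =, D_slow =, D_fast =)`: layer half-
#'   thickness (um, per side) and the slow/fast diffusivities (mm^2/s)
#' @param evolution optional `list(time_ms =, scale =)` schedule
#' @param instances optional k x 3 matrix of instance translations (um)
#' @return an object of class `membrane`
#' @export
membrane <- function(mesh, permeability = 0, polar = NULL, evolution = NULL,
                     instances = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (permeability < 0 || permeability > 1)
    stop("permeability must be in [0, 1]")
  if (!is.null(polar)) {
    stopifnot(all(c("h_um", "D_slow", "D_fast") %in% names(polar)))
    if (polar$h_um < 0) stop("polar layer thickness must be >= 0")
    if (polar$D_slow > polar$D_fast) stop("polar layer requires D_slow <= D_fast")
  }
  if (!is.null(instances)) {
    instances <- as.matrix(instances)
    stopifnot(ncol(instances) == 3)
  }
  structure(list(mesh = mesh, permeability = permeability, polar = polar,
                 evolution = evolution, instances = instances),
            class = "membrane")
}

n_instances <- function(m) if (is.null(m$instances)) 1L else nrow(m$instances)

#' Simulation scene: a bounded box of membranes
#'
#' The scene is the world of the Monte Carlo simulation: an axis-aligned box
#' `[0, Lx] x [0, Ly] x [0, Lz]` (um) holding a list of membranes. The outer
#' boundary is either `"reflective"` (walkers bounce off the walls, the
#' default) or `"periodic"` (walkers wrap around).
#'
#' @param bounds numeric length-3: box edge lengths (um)
#' @param membranes list of [membrane()] objects (may be empty)
#' @param boundary `"reflective"` or `"periodic"`
#' @return an object of class `scene`
#' @export
scene <- function(bounds, membranes = list(), boundary = c("reflective", "periodic")) {
  boundary <- match.arg(boundary)
  bounds <- as.numeric(bounds)
  stopifnot(length(bounds) == 3, all(bounds > 0))
  if (inherits(membranes, "membrane")) membranes <- list(membranes)
  stopifnot(all(vapply(membranes, inherits, TRUE, "membrane")))
  structure(list(bounds = bounds, membranes = membranes, boundary = boundary),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  ninst <- sum(vapply(x$membranes, n_instances, 1L))
  ntri <- sum(vapply(x$membranes,
                     function(m) nrow(m$mesh$triangles) * n_instances(m), 1L))
  cat(sprintf("scene: %.4g x %.4g x %.4g um^3, %d membrane instance(s), %d triangles, %s boundary\n",
              x$bounds[1], x$bounds[2], x$bounds[3], ninst, ntri, x$boundary))
  invisible(x)
}

# hexagonal in-plane lattice positions: columns at `spacing`, rows at
# spacing*sqrt(3)/2 with alternate rows offset by spacing/2
hex_rows <- function(n_rows, n_cols, spacing) {
  dy <- spacing * sqrt(3) / 2
  do.call(rbind, lapply(seq_len(n_rows) - 1L, function(j) {
    cbind((seq_len(n_cols) - 1L) * spacing + (j %% 2) * spacing / 2,
          j * dy)
  }))
}

#' Hexagonal lattice of parallel cylindrical fibers
#'
#' `rows x cols` parallel fibers of the given diameter along the z axis,
#' placed on an offset-row (hexagonal) lattice with the given center spacing.
#' The scene box defaults to the lattice extent plus a half-spacing margin,
#' or can be fixed explicitly (the fiber bundle is then centered in x/y).
#'
#' @param rows,cols lattice dimensions
#' @param diameter fiber diameter (um)
#' @param spacing center-to-center spacing (um); must be >= diameter
#' @param length fiber length (um); also the box z extent
#' @param bounds optional explicit box edge lengths (um)
#' @param n_facets facets per cylinder circumference (20: 40 side triangles)
#' @param permeability membrane permeability
#' @param boundary scene boundary mode (see [scene()])
#' @return a [scene()]
#' @export
make_hexagonal_cylinder_lattice <- function(rows, cols, diameter, spacing, length,
                                            bounds = NULL, n_facets = 20,
                                            permeability = 0,
                                            boundary = "reflective") {
  if (spacing < diameter)
    stop("overlapping cylinders: spacing < diameter")
  xy <- hex_rows(rows, cols, spacing)
  ext <- c(max(xy[, 1]) - min(xy[, 1]), max(xy[, 2]) - min(xy[, 2]))
  if (is.null(bounds)) bounds <- c(ext + spacing, length)
  off <- c((bounds[1] - ext[1]) / 2, (bounds[2] - ext[2]) / 2)
  centers <- cbind(sweep(xy, 2, off - c(min(xy[, 1]), min(xy[, 2])), `+`), 0)
  template <- make_cylinder_mesh(rbind(c(0, 0, 0), c(0, 0, length)),
                                 diameter / 2, n_facets)
  m <- membrane(template, permeability = permeability, instances = centers)
  s <- scene(bounds, list(m), boundary = boundary)
  attr(s, "lattice") <- list(type = "cylinder", n = nrow(centers),
                             R = diameter / 2, L = length, spacing = spacing)
  s
}

#' Hexagonal lattice of spherical cells
#'
#' Fills the box with a hexagonally close-packed arrangement of sphere
#' centers at the given spacing (offset rows in-plane, ABAB layer stacking,
#' nearest-center distance exactly `spacing`). When `n_spheres` is given, the
#' innermost `n_spheres` centers (by scaled Chebyshev distance from the box
#' center) are kept, trimming a thin outer shell; this pins the cell count
#' of a lattice that does not tile the box exactly.
#'
#' @param bounds box edge lengths (um)
#' @param R sphere radius (um); requires 2R <= spacing
#' @param spacing center spacing (um)
#' @param n_spheres optional exact number of spheres to keep
#' @param level icosphere subdivision level
#' @param permeability membrane permeability
#' @param polar optional polar-layer spec (see [membrane()])
#' @param boundary scene boundary mode (see [scene()])
#' @return a [scene()]
#' @export
make_hexagonal_sphere_lattice <- function(bounds, R, spacing, n_spheres = NULL,
                                          level = 3, permeability = 0,
                                          polar = NULL,
                                          boundary = "reflective") {
  if (2 * R > spacing) stop("overlapping spheres: 2R > spacing")
  bounds <- as.numeric(bounds)
  dy <- spacing * sqrt(3) / 2
  dz <- spacing * sqrt(2 / 3)
  nx <- floor(bounds[1] / spacing + 1e-9) + 1
  ny <- floor(bounds[2] / dy + 1e-9) + 1
  nz <- floor(bounds[3] / dz + 1e-9) + 1
  x0 <- (bounds[1] - (nx - 1) * spacing) / 2
  y0 <- (bounds[2] - (ny - 1) * dy) / 2
  z0 <- (bounds[3] - (nz - 1) * dz) / 2
  centers <- list()
  for (l in seq_len(nz) - 1L) {
    loff <- if (l %% 2 == 1) c(spacing / 2, dy / 3) else c(0, 0)
    for (j in seq_len(ny) - 1L) {
      xs <- x0 + (seq_len(nx) - 1L) * spacing + (j %% 2) * spacing / 2 + loff[1]
      ys <- y0 + j * dy + loff[2]
      zs <- z0 + l * dz
      keep <- xs >= 0 & xs <= bounds[1]
      if (ys >= 0 && ys <= bounds[2] && any(keep))
        centers[[length(centers) + 1]] <- cbind(xs[keep], ys, zs)
    }
  }
  centers <- do.call(rbind, centers)
  if (!is.null(n_spheres)) {
    if (n_spheres > nrow(centers))
      stop(sprintf("lattice holds only %d centers; %d requested",
                   nrow(centers), n_spheres))
    d <- apply(abs(sweep(centers, 2, bounds / 2, `-`)) / (bounds / 2), 1, max)
    centers <- centers[order(d)[seq_len(n_spheres)], , drop = FALSE]
  }
  template <- make_sphere_mesh(c(0, 0, 0), R, level)
  m <- membrane(template, permeability = permeability, polar = polar,
                instances = centers)
  s <- scene(bounds, list(m), boundary = boundary)
  attr(s, "lattice") <- list(type = "sphere", n = nrow(centers), R = R,
                             spacing = spacing)
  s
}

#' Cubic grid of spherical cells
#'
#' Simple cubic arrangement (used by the grid-scaling benchmark scene).
#'
#' @param n number of spheres per axis
#' @param R sphere radius (um)
#' @param spacing center spacing (um)
#' @param bounds box edge lengths (um); centers are centered in the box
#' @param level icosphere subdivision level
#' @param permeability membrane permeability
#' @return a [scene()]
#' @export
make_cubic_sphere_grid <- function(n, R, spacing, bounds, level = 3,
                                   permeability = 0) {
  if (2 * R > spacing) stop("overlapping spheres: 2R > spacing")
  bounds <- as.numeric(bounds)
  g <- (seq_len(n) - (n + 1) / 2) * spacing
  centers <- as.matrix(expand.grid(x = g + bounds[1] / 2, y = g + bounds[2] / 2,
                                   z = g + bounds[3] / 2))
  template <- make_sphere_mesh(c(0, 0, 0), R, level)
  m <- membrane(template, permeability = permeability, instances = centers)
  s <- scene(bounds, list(m))
  attr(s, "lattice") <- list(type = "sphere", n = nrow(centers), R = R,
                             spacing = spacing)
  s
}

#' Crossing, kissing, and branching fiber phantoms
#'
#' Two interleaved networks of impermeable fibers in fixed simulation boxes:
#' `crossing` and `kissing` in 110 x 190 x 150 um^3, `branching` in
#' 200 x 210 x 185 um^3, all with 5 um fiber diameter. The exact angles and
#' curvatures are package constants chosen to produce the named topology:
#' crossing bundles intersect the mid-plane at +/-35 degrees, kissing bundles
#' are circular arcs tangent at the midline, and the branching network splits
#' a trunk into two limbs.
#'
#' @param kind `"crossing"`, `"kissing"`, or `"branching"`
#' @param diameter fiber diameter (um)
#' @param n_per_bundle fibers per bundle (in-plane stack count)
#' @param n_facets facets per cylinder circumference
#' @return a [scene()]
#' @export
make_fiber_configuration <- function(kind = c("crossing", "kissing", "branching"),
                                     diameter = 5, n_per_bundle = 12,
                                     n_facets = 12) {
  kind <- match.arg(kind)
  R <- diameter / 2
  spacing <- diameter * 1.04
  mk_bundle <- function(curve_fun, n, z_vals) {
    lapply(z_vals, function(z0) {
      crv <- curve_fun(z0)
      make_cylinder_mesh(crv, R, n_facets)
    })
  }
  if (kind %in% c("crossing", "kissing")) {
    bounds <- c(110, 190, 150)
    zs <- bounds[3] / 2 + (seq_len(n_per_bundle) - (n_per_bundle + 1) / 2) * spacing
    # interleave: odd slots bundle 1, even slots bundle 2
    z1 <- zs[seq(1, length(zs), 2)]
    z2 <- zs[seq(2, length(zs), 2)]
    if (kind == "crossing") {
      ang <- 35 * pi / 180
      f1 <- function(z0) {
        t <- seq(-1, 1, length.out = 2)
        cbind(bounds[1] / 2 + t * 0, bounds[2] / 2 + t * (bounds[2] / 2 - R - 1), z0)
      }
      # bundle 2 crosses at `ang` to bundle 1 within the x-y plane
      f2 <- function(z0) {
        t <- seq(-1, 1, length.out = 2)
        L <- bounds[2] / 2 - R - 1
        cbind(bounds[1] / 2 + t * L * sin(ang), bounds[2] / 2 + t * L * cos(ang), z0)
      }
      meshes <- c(mk_bundle(f1, n_per_bundle, z1), mk_bundle(f2, n_per_bundle, z2))
    } else {
      # kissing: two arcs tangent to the midline x = Lx/2, bending apart
      arc <- function(sgn) function(z0) {
        s <- seq(-1, 1, length.out = 17)
        L <- bounds[2] / 2 - R - 1
        curv <- 28     # sagitta of the arc (um)
        cbind(bounds[1] / 2 + sgn * curv * s^2, bounds[2] / 2 + s * L, z0)
      }
      meshes <- c(mk_bundle(arc(+1), n_per_bundle, z1),
                  mk_bundle(arc(-1), n_per_bundle, z2))
    }
  } else {
    bounds <- c(200, 210, 185)
    zs <- bounds[3] / 2 + (seq_len(n_per_bundle) - (n_per_bundle + 1) / 2) * spacing
    z1 <- zs[seq(1, length(zs), 2)]
    z2 <- zs[seq(2, length(zs), 2)]
    # trunk enters at low y and splits: limbs diverge in +x and -x
    limb <- function(sgn) function(z0) {
      s <- seq(0, 1, length.out = 17)
      yb <- bounds[2] * 0.45
      y <- 4 + s * (bounds[2] - 8)
      x <- bounds[1] / 2 + sgn * pmax(0, y - yb)^2 / (2.2 * (bounds[2] - yb))
      cbind(x, y, z0)
    }
    meshes <- c(mk_bundle(limb(+1), n_per_bundle, z1),
                mk_bundle(limb(-1), n_per_bundle, z2))
  }
  membranes <- lapply(meshes, membrane, permeability = 0)
  s <- scene(bounds, membranes)
  attr(s, "fiber_kind") <- kind
  s
}

#' Intracellular volume fraction of a scene
#'
#' Total enclosed membrane volume divided by the box volume. For scenes built
#' by the parametric lattice generators the analytic shape volume is used
#' (count x (4/3) pi R^3 for spheres, count x pi R^2 L for cylinders);
#' otherwise the divergence-theorem mesh volume is summed over instances.
#'
#' @param scene a [scene()]
#' @return fraction in \[0, 1\]
#' @export
intracellular_volume_fraction <- function(scene) {
  if (length(scene$membranes) == 0) return(0)
  total <- 0
  for (m in scene$membranes) {
    shp <- attr(m$mesh, "shape")
    vol <- if (!is.null(shp) && shp$type == "sphere") {
      4 / 3 * pi * shp$R^3
    } else if (!is.null(shp) && shp$type == "cylinder") {
      pi * shp$R^2 * shp$L
    } else {
      if (!mesh_is_closed(m$mesh)) stop("open mesh: volume fraction undefined")
      mesh_volume(m$mesh)
    }
    total <- total + vol * n_instances(m)
  }
  total / prod(scene$bounds)
}

# ---------------------------------------------------------------------------
# Scene config (YAML) serialization
# ---------------------------------------------------------------------------

#' Write and read scene configurations
#'
#' Scenes built from the parametric generators serialize to a YAML config
#' listing the generator and its parameters (plus membrane properties and
#' subvolume dims); generic mesh scenes store mesh file references.
#'
#' @param config a named list (e.g. from [make_fixture()])
#' @param path file path
#' @return `read_config` returns the config list
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
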