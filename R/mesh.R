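#' Triangle mesh surfaces
#'
#' A `triangle_mesh` is a closed, orientable triangulated surface used to
#' model a cell membrane. Vertices are 3D positions in micrometres; triangles
#' are 1-based vertex-index triples wound counter-clockwise when seen from
#' outside, so face normals point away from the enclosed interior.
#'
#' @param vertices numeric matrix (n x 3) of vertex positions (um)
#' @param triangles integer matrix (m x 3) of 1-based vertex indices
#' @return an object of class `triangle_mesh`
#' @export
triangle_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3,
            min(triangles) >= 1, max(triangles) <= nrow(vertices))
  structure(list(vertices = vertices, triangles = triangles),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d triangles, enclosed volume %.4g um^3\n",
              nrow(x$vertices), nrow(x$triangles), mesh_volume(x)))
  invisible(x)
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume by the divergence theorem (sum of signed tetrahedra against
#' the origin). Positive for outward-oriented closed surfaces.
#'
#' @param mesh a [triangle_mesh()]
#' @return volume in um^3
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c_ <- v[tr[, 3], , drop = FALSE]
  det <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
         a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
         a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(det) / 6
}

#' Face normals of a mesh
#'
#' @param mesh a [triangle_mesh()]
#' @param normalize return unit normals
#' @return m x 3 matrix of (unit) face normals
#' @export
mesh_face_normals <- function(mesh, normalize = TRUE) {
  v <- mesh$vertices
  tr <- mesh$triangles
  e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  if (normalize) n <- n / sqrt(rowSums(n^2))
  n
}

#' Check that a mesh is closed (every edge shared by exactly two triangles)
#'
#' @param mesh a [triangle_mesh()]
#' @return logical
#' @export
mesh_is_closed <- function(mesh) {
  tr <- mesh$triangles
  edges <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  all(table(key) == 2L)
}

orient_outward <- function(mesh) {
  if (mesh_volume(mesh) < 0)
    mesh$triangles <- mesh$triangles[, c(1, 3, 2)]
  mesh
}

#' Icosphere membrane mesh
#'
#' Builds a closed sphere mesh by recursive midpoint subdivision of an
#' icosahedron, projecting new vertices back to the sphere. The enclosed
#' volume converges to (4/3) pi R^3 from below as `level` grows (the
#' subdivision-level-3 mesh is within 1% of the analytic volume).
#'
#' @param center sphere center (um)
#' @param R radius (um), must be positive
#' @param level number of subdivision passes (default 3: 1280 triangles)
#' @return a [triangle_mesh()] with a `shape` attribute recording the
#'   parametric description (used for analytic volume computations)
#' @export
make_sphere_mesh <- function(center = c(0, 0, 0), R, level = 3) {
  if (!is.numeric(R) || length(R) != 1 || R <= 0)
    stop("sphere radius must be a single positive number")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(level)) {
    nv <- nrow(v)
    edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    mids <- new.env(hash = TRUE)
    newf <- matrix(0L, nrow(f) * 4, 3)
    newv <- list()
    midpoint <- function(i, j) {
      k <- edge_key(i, j)
      id <- mids[[k]]
      if (is.null(id)) {
        m <- (v[i, ] + v[j, ]) / 2
        m <- m / sqrt(sum(m^2))
        newv[[length(newv) + 1]] <<- m
        id <- nv + length(newv)
        mids[[k]] <- id
      }
      id
    }
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[4 * t - 3, ] <- c(a, ab, ca)
      newf[4 * t - 2, ] <- c(b, bc, ab)
      newf[4 * t - 1, ] <- c(cc, ca, bc)
      newf[4 * t, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  mesh <- triangle_mesh(sweep(v * R, 2, center, `+`), f)
  mesh <- orient_outward(mesh)
  attr(mesh, "shape") <- list(type = "sphere", center = center, R = R)
  mesh
}

#' Capped cylinder (tube) membrane mesh along a 3D axis curve
#'
#' The tube follows the polyline `axis_curve` with circular cross sections of
#' radius `R`, using parallel-transported frames so the cross sections do not
#' twist along curved axes. End caps are closed with triangle fans. A straight
#' two-point axis produces `2 * n_facets` side triangles.
#'
#' @param axis_curve k x 3 matrix of polyline nodes (um), k >= 2
#' @param R tube radius (um)
#' @param n_facets number of facets around the circumference (>= 3)
#' @return a closed [triangle_mesh()] with a `shape` attribute when the axis
#'   is straight
#' @export
make_cylinder_mesh <- function(axis_curve, R, n_facets = 20) {
  axis_curve <- as.matrix(axis_curve)
  if (nrow(axis_curve) < 2) stop("axis_curve needs at least two nodes")
  if (R <= 0) stop("cylinder radius must be positive")
  if (n_facets < 3) stop("n_facets must be at least 3")
  seg <- diff(axis_curve)
  seg_len <- sqrt(rowSums(seg^2))
  if (any(seg_len == 0) || sum(seg_len) == 0) stop("degenerate (zero-length) axis")
  tang <- seg / seg_len

  k <- nrow(axis_curve)
  # node tangents: average of adjacent segment tangents
  ntan <- matrix(0, k, 3)
  ntan[1, ] <- tang[1, ]
  ntan[k, ] <- tang[k - 1, ]
  if (k > 2)
    for (i in 2:(k - 1)) {
      tm <- tang[i - 1, ] + tang[i, ]
      ntan[i, ] <- tm / sqrt(sum(tm^2))
    }
  # parallel-transported frame
  ref <- if (abs(ntan[1, 1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  n1 <- ref - sum(ref * ntan[1, ]) * ntan[1, ]
  n1 <- n1 / sqrt(sum(n1^2))
  frames <- vector("list", k)
  frames[[1]] <- n1
  for (i in 2:k) {
    prev <- frames[[i - 1]]
    ti <- ntan[i, ]
    n_i <- prev - sum(prev * ti) * ti
    nn <- sqrt(sum(n_i^2))
    if (nn < 1e-12) stop("axis curvature too sharp for frame transport")
    frames[[i]] <- n_i / nn
  }

  ang <- 2 * pi * (seq_len(n_facets) - 1) / n_facets
  verts <- matrix(0, k * n_facets + 2, 3)
  for (i in seq_len(k)) {
    ti <- ntan[i, ]
    ni <- frames[[i]]
    bi <- c(ti[2] * ni[3] - ti[3] * ni[2],
            ti[3] * ni[1] - ti[1] * ni[3],
            ti[1] * ni[2] - ti[2] * ni[1])
    ring <- outer(cos(ang), ni) + outer(sin(ang), bi)
    verts[(i - 1) * n_facets + seq_len(n_facets), ] <-
      sweep(R * ring, 2, axis_curve[i, ], `+`)
  }
  c0 <- k * n_facets + 1   # start cap center
  c1 <- k * n_facets + 2   # end cap center
  verts[c0, ] <- axis_curve[1, ]
  verts[c1, ] <- axis_curve[k, ]

  tris <- list()
  for (i in seq_len(k - 1)) {
    a <- (i - 1) * n_facets + seq_len(n_facets)
    b <- a %% (n_facets) + (i - 1) * n_facets + 1   # next around ring
    a2 <- a + n_facets
    b2 <- b + n_facets
    tris[[length(tris) + 1]] <- cbind(a, b, a2)
    tris[[length(tris) + 1]] <- cbind(b, b2, a2)
  }
  ring1 <- seq_len(n_facets)
  ringk <- (k - 1) * n_facets + seq_len(n_facets)
  nxt <- c(seq_len(n_facets)[-1], 1)
  tris[[length(tris) + 1]] <- cbind(rep(c0, n_facets), ring1[nxt], ring1)
  tris[[length(tris) + 1]] <- cbind(rep(c1, n_facets), ringk, ringk[nxt])
  mesh <- triangle_mesh(verts, do.call(rbind, tris))
  mesh <- orient_outward(mesh)
  # volume check catches gross self-intersection of over-curved tubes
  if (mesh_volume(mesh) <= 0) stop("cylinder mesh degenerate (self-intersecting?)")
  if (k == 2) {
    L <- sum(seg_len)
    attr(mesh, "shape") <- list(type = "cylinder", p0 = axis_curve[1, ],
                                p1 = axis_curve[2, ], R = R, L = L)
  }
  mesh
}

#' Morphological evolution of a membrane mesh
#'
#' Applies a membrane's evolution schedule (time -> isotropic scale factor) at
#' time `t`: vertices are scaled about the mesh centroid, so the enclosed
#' volume scales with the cube of the factor. Times outside the schedule are
#' clamped to the nearest endpoint with a message. Triangle connectivity is
#' untouched.
#'
#' @param membrane a [membrane()] carrying an `evolution` schedule
#'   (`list(time_ms = ..., scale = ...)`)
#' @param t time (ms)
#' @return the evolved [triangle_mesh()]
#' @export
evolve_morphology <- function(membrane, t) {
  ev <- membrane$evolution
  if (is.null(ev)) stop("membrane has no evolution schedule")
  tr <- range(ev$time_ms)
  if (t < tr[1] || t > tr[2]) {
    message(sprintf("evolution time %g ms outside schedule [%g, %g]; clamping",
                    t, tr[1], tr[2]))
    t <- min(max(t, tr[1]), tr[2])
  }
  f <- approx(ev$time_ms, ev$scale, xout = t, rule = 2)$y
  mesh <- membrane$mesh
  ctr <- colMeans(mesh$vertices)
  mesh$vertices <- sweep(sweep(mesh$vertices, 2, ctr, `-`) * f, 2, ctr, `+`)
  shp <- attr(mesh, "shape")
  if (!is.null(shp) && shp$type == "sphere") {
    shp$R <- shp$R * f
    attr(mesh, "shape") <- shp
  }
  mesh
}

# ---------------------------------------------------------------------------
# Mesh file I/O: OFF and ASCII PLY
# ---------------------------------------------------------------------------

#' Read and write triangle meshes in OFF or PLY format
#'
#' Plain-text OFF and ASCII PLY, the two simplest standard polygon formats.
#' Only triangular faces are supported.
#'
#' @param mesh a [triangle_mesh()]
#' @param path file path; format chosen by extension (`.off` or `.ply`)
#' @return `read_mesh` returns a [triangle_mesh()]; `write_mesh` returns the
#'   path invisibly
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  if (ext == "off") {
    writeLines(c("OFF", sprintf("%d %d 0", nv, nf)), con)
    write.table(format(mesh$vertices, digits = 17, trim = TRUE, scientific = FALSE),
                con, row.names = FALSE, col.names = FALSE, quote = FALSE)
    write.table(cbind(3L, mesh$triangles - 1L), con,
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else if (ext == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nv),
                 "property double x", "property double y", "property double z",
                 sprintf("element face %d", nf),
                 "property list uchar int vertex_indices", "end_header"), con)
    write.table(format(mesh$vertices, digits = 17, trim = TRUE, scientific = FALSE),
                con, row.names = FALSE, col.names = FALSE, quote = FALSE)
    write.table(cbind(3L, mesh$triangles - 1L), con,
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else stop("unsupported mesh format: ", ext)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (ext == "off") {
    stopifnot(trimws(lines[1]) == "OFF")
    hdr <- scan(text = lines[2], quiet = TRUE)
    nv <- hdr[1]; nf <- hdr[2]
    v <- matrix(scan(text = lines[3:(2 + nv)], quiet = TRUE), nv, 3, byrow = TRUE)
    f <- matrix(scan(text = lines[(3 + nv):(2 + nv + nf)], quiet = TRUE), nf, 4,
                byrow = TRUE)
    stopifnot(all(f[, 1] == 3))
    triangle_mesh(v, f[, 2:4] + 1L)
  } else if (ext == "ply") {
    end <- which(trimws(lines) == "end_header")
    nv <- as.integer(sub(".*element vertex ", "", grep("element vertex", lines, value = TRUE)))
    nf <- as.integer(sub(".*element face ", "", grep("element face", lines, value = TRUE)))
    v <- matrix(scan(text = lines[end + seq_len(nv)], quiet = TRUE), nv, 3, byrow = TRUE)
    f <- matrix(scan(text = lines[end + nv + seq_len(nf)], quiet = TRUE), nf, 4,
                byrow = TRUE)
    stopifnot(all(f[, 1] == 3))
    triangle_mesh(v, f[, 2:4] + 1L)
  } else stop("unsupported mesh format: ", ext)
}
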