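# Independent oracles and shared fixtures for the test suite.

# Brute-force first-intersection over all triangles of a scene (vectorized
# Moller-Trumbore in R), independent of the compiled grid traversal.
flatten_scene_triangles <- function(scene) {
  v0 <- v1 <- v2 <- NULL
  for (m in scene$membranes) {
    mesh <- m$mesh
    inst <- if (is.null(m$instances)) matrix(0, 1, 3) else m$instances
    for (k in seq_len(nrow(inst))) {
      v0 <- rbind(v0, sweep(mesh$vertices[mesh$triangles[, 1], , drop = FALSE], 2, inst[k, ], `+`))
      v1 <- rbind(v1, sweep(mesh$vertices[mesh$triangles[, 2], , drop = FALSE], 2, inst[k, ], `+`))
      v2 <- rbind(v2, sweep(mesh$vertices[mesh$triangles[, 3], , drop = FALSE], 2, inst[k, ], `+`))
    }
  }
  list(v0 = v0, v1 = v1, v2 = v2)
}

brute_first_intersection <- function(tris, p0, p1) {
  d <- p1 - p0
  e1 <- tris$v1 - tris$v0
  e2 <- tris$v2 - tris$v0
  pv <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
              d[3] * e2[, 1] - d[1] * e2[, 3],
              d[1] * e2[, 2] - d[2] * e2[, 1])
  det <- rowSums(e1 * pv)
  tv <- sweep(-tris$v0, 2, p0, `+`)
  u <- rowSums(tv * pv) / det
  qv <- cbind(tv[, 2] * e1[, 3] - tv[, 3] * e1[, 2],
              tv[, 3] * e1[, 1] - tv[, 1] * e1[, 3],
              tv[, 1] * e1[, 2] - tv[, 2] * e1[, 1])
  v <- (qv[, 1] * d[1] + qv[, 2] * d[2] + qv[, 3] * d[3]) / det
  t <- rowSums(e2 * qv) / det
  ok <- abs(det) > 1e-300 & u >= -1e-12 & u <= 1 + 1e-12 &
        v >= -1e-12 & u + v <= 1 + 1e-12 & t > 1e-12 & t <= 1
  if (!any(ok)) return(NULL)
  min(t[ok])
}

# Monte Carlo oracle: E |X - Y|^2 for X, Y uniform in a ball of radius a
two_points_in_ball_msd <- function(a, n = 2e5, seed = 99) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    sample_ball <- function(k) {
      p <- matrix(rnorm(3 * k), k, 3)
      p <- p / sqrt(rowSums(p^2))
      p * a * runif(k)^(1 / 3)
    }
    x <- sample_ball(n)
    y <- sample_ball(n)
    mean(rowSums((x - y)^2))
  })
}

# small shared direction tables (lazy, cached per session)
.test_cache <- new.env(parent = emptyenv())
test_table <- function(n = 128, seed = 5) {
  key <- sprintf("t%d_%d", n, seed)
  if (is.null(.test_cache[[key]]))
    .test_cache[[key]] <- generate_direction_table(n, iterations = 400, seed = seed)
  .test_cache[[key]]
}

# canonical small test scenes
single_sphere_scene <- function(R = 4, box = 20, level = 3, ...) {
  m <- membrane(make_sphere_mesh(rep(box / 2, 3), R, level), ...)
  scene(rep(box, 3), list(m))
}

# Closed-form Stejskal-Tanner b-value for a trapezoidal PGSE,
# delta = ramp-up start to ramp-down start, eps = G/S_R
stejskal_tanner_b <- function(G_mTm, delta_ms, Delta_ms, S_R = Inf) {
  gam <- 2.675e8
  g <- G_mTm * 1e-3
  d <- delta_ms * 1e-3
  D <- Delta_ms * 1e-3
  e <- if (is.finite(S_R)) g / S_R else 0
  b <- gam^2 * g^2 * (d^2 * (D - d / 3) + e^3 / 30 - d * e^2 / 6)
  b * 1e-6   # s/mm^2
}
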