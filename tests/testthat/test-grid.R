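cluttered_scene <- function() {
  cents <- as.matrix(expand.grid(x = c(5, 15, 25), y = c(5, 15, 25),
                                 z = c(5, 15, 25)))
  m <- membrane(make_sphere_mesh(c(0, 0, 0), 4, 2), instances = cents)
  scene(c(30, 30, 30), list(m))
}

test_that("every triangle is registered in at least one grid cell", {
  sc <- cluttered_scene()
  g <- build_subvolume_grid(sc, c(7, 7, 7))
  expect_gte(g$stats$n_registrations, g$stats$n_triangles)
  # empty scene: grid holds nothing
  g0 <- build_subvolume_grid(scene(c(10, 10, 10)), c(4, 4, 4))
  expect_identical(g0$stats$n_registrations, 0)
})

test_that("grid-accelerated intersections match brute force on random segments", {
  sc <- cluttered_scene()
  g <- build_subvolume_grid(sc, c(12, 12, 12))
  tris <- flatten_scene_triangles(sc)
  set.seed(42)
  n_mismatch <- 0
  max_diff <- 0
  for (i in 1:1000) {
    p0 <- runif(3, 0.5, 29.5)
    p1 <- pmin(pmax(p0 + runif(3, -4, 4), 0.1), 29.9)
    h <- first_intersection(g, p0, p1)
    tb <- brute_first_intersection(tris, p0, p1)
    if (is.null(tb) != !h$hit) n_mismatch <- n_mismatch + 1
    else if (h$hit) max_diff <- max(max_diff, abs(h$t - tb))
  }
  expect_identical(n_mismatch, 0)
  expect_lt(max_diff * 30, 1e-9 * sqrt(3) * 30)   # within 1e-9 of scene scale
})

test_that("finer grids cut the candidate tests per query", {
  sc <- make_cubic_sphere_grid(15, 5, 10, c(150, 150, 150), level = 2)
  g_coarse <- build_subvolume_grid(sc, c(10, 10, 10))
  g_fine <- build_subvolume_grid(sc, c(50, 50, 50))
  set.seed(7)
  tested <- c(coarse = 0, fine = 0)
  for (i in 1:200) {
    p0 <- runif(3, 1, 149)
    p1 <- pmin(pmax(p0 + runif(3, -1, 1), 0.5), 149.5)
    hc <- first_intersection(g_coarse, p0, p1)
    hf <- first_intersection(g_fine, p0, p1)
    expect_identical(hc$hit, hf$hit)
    if (hc$hit) expect_equal(hc$t, hf$t, tolerance = 1e-12)
    tested["coarse"] <- tested["coarse"] + hc$tested
    tested["fine"] <- tested["fine"] + hf$tested
  }
  expect_gte(tested[["coarse"]] / max(tested[["fine"]], 1), 3)
})

test_that("first_intersection honors orthogonal and contained segments", {
  # one triangle crossed orthogonally through its centroid
  tri <- triangle_mesh(rbind(c(0, 0, 5), c(10, 0, 5), c(0, 10, 5),
                             c(10, 10, 5.0001)),
                       rbind(c(1, 2, 3), c(2, 4, 3), c(1, 3, 2), c(2, 3, 4)))
  sc <- scene(c(10, 10, 10), list(membrane(tri)))
  g <- build_subvolume_grid(sc, c(4, 4, 4))
  centroid <- colMeans(rbind(c(0, 0, 5), c(10, 0, 5), c(0, 10, 5)))
  h <- first_intersection(g, c(centroid[1], centroid[2], 2),
                          c(centroid[1], centroid[2], 8))
  expect_true(h$hit)
  expect_equal(h$point, centroid, tolerance = 1e-12, ignore_attr = TRUE)

  # segment fully inside a sphere, shorter than the distance to the wall
  sc2 <- single_sphere_scene(R = 4, box = 20)
  g2 <- build_subvolume_grid(sc2, c(8, 8, 8))
  h2 <- first_intersection(g2, c(10, 10, 10), c(10.5, 10, 10))
  expect_false(h2$hit)

  # degenerate zero-length segment
  expect_false(first_intersection(g2, c(10, 10, 10), c(10, 10, 10))$hit)
})

test_that("locate_points and surface_distance agree with sphere geometry", {
  sc <- single_sphere_scene(R = 4, box = 20)
  g <- build_subvolume_grid(sc, c(10, 10, 10))
  set.seed(3)
  pts <- matrix(runif(300, 2, 18), ncol = 3)
  r <- sqrt(rowSums(sweep(pts, 2, c(10, 10, 10), `-`)^2))
  inside <- !is.na(locate_points(g, pts))
  expect_identical(inside[r < 3.9], rep(TRUE, sum(r < 3.9)))
  expect_identical(inside[r > 4.1], rep(FALSE, sum(r > 4.1)))
  d <- surface_distance(g, pts, radius = 6)
  near <- is.finite(d)
  expect_equal(d[near], abs(r - 4)[near], tolerance = 0.02)
})
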