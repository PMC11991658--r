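sample_rectangle <- function(lx = 40, ly = 20, spacing = 0.8, seed = 41,
                             jitter = 0.25) {
  set.seed(seed)
  g <- expand.grid(x = seq(0, lx, by = spacing), y = seq(0, ly, by = spacing))
  g$x <- pmin(pmax(g$x + runif(nrow(g), -jitter, jitter) * spacing, 0), lx)
  g$y <- pmin(pmax(g$y + runif(nrow(g), -jitter, jitter) * spacing, 0), ly)
  point_cloud(cbind(g$x, g$y, 0))
}

test_that("mesh area sums triangle areas (unit right triangle, icosahedron faces)", {
  tri <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), matrix(1:3, 1))
  expect_equal(mesh_area(tri), 0.5)
  # regular icosahedron with circumradius 1: area = 5 * sqrt(3) * a^2 with
  # a = 4 / sqrt(10 + 2 sqrt(5))
  phi <- (1 + sqrt(5)) / 2
  verts <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  verts <- verts / sqrt(1 + phi^2)
  faces <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  ico <- tri_mesh(verts, faces)
  a <- 4 / sqrt(10 + 2 * sqrt(5))
  expect_equal(mesh_area(ico), 5 * sqrt(3) * a^2, tolerance = 1e-9)
})

test_that("tri_mesh validates face indices and degeneracy", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(tri_mesh(v, matrix(c(1, 2, 4), 1)), "range")
  expect_error(tri_mesh(v, matrix(c(1, 2, 2), 1)), "degenerate")
})

test_that("boundary edges: open triangle has three, interior edges are dropped", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  one <- tri_mesh(v[1:3, ], matrix(1:3, 1))
  expect_equal(nrow(boundary_edges(one)), 3)
  quad <- tri_mesh(v, rbind(c(1, 2, 3), c(2, 4, 3)))
  be <- boundary_edges(quad)
  expect_equal(nrow(be), 4) # the shared diagonal 2-3 is interior
  expect_false(any(be[, 1] == 2 & be[, 2] == 3))
})

test_that("reconstructing a planar rectangle recovers its area within 10 percent", {
  rect <- sample_rectangle()
  mesh <- reconstruct_leaf_mesh(rect)
  expect_s3_class(mesh, "tri_mesh")
  expect_equal(mesh_area(mesh), 800, tolerance = 0.1)
  expect_error(reconstruct_leaf_mesh(point_cloud(matrix(rnorm(30), 10))),
               "at least 100")
  line <- cbind(seq(0, 99.9, 0.1), 0, 0)
  expect_error(reconstruct_leaf_mesh(point_cloud(line)), "collinear")
})

test_that("leaf-edge segmentation returns the perimeter band of a rectangle", {
  rect <- sample_rectangle()
  seg <- segment_leaf_edges(rect, d_th_mm = 4)
  expect_gt(n_points(seg$edge_cloud), 0)
  # subset property
  expect_true(all(seg$edge_index %in% seq_len(n_points(rect))))
  # analytic perimeter-distance oracle for the 40 x 20 rectangle
  perim_dist <- function(p) pmin(p[, 1], 40 - p[, 1], p[, 2], 20 - p[, 2])
  expect_true(all(perim_dist(seg$edge_cloud$points) <= 4 + 1.0))
  # interior points far from the perimeter are excluded
  interior <- perim_dist(rect$points) > 5.5
  expect_false(any(seg$edge_index %in% which(interior)))
})

test_that("curved leaf patches mesh to within a few percent of the analytic area", {
  # paraboloid z = (x^2 + y^2) / 60 over a 30 mm disc; analytic area by the
  # surface-of-revolution integral: 2 pi c^2 / 3 * ((1 + r^2/c^2)^1.5 - 1),
  # c = 30
  set.seed(43)
  n <- 6000
  r <- 15 * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  x <- r * cos(th); y <- r * sin(th)
  cloud <- point_cloud(cbind(x, y, (x^2 + y^2) / 60))
  analytic <- 2 * pi * 30^2 / 3 * ((1 + 15^2 / 30^2)^1.5 - 1)
  expect_equal(leaf_area(cloud), analytic, tolerance = 0.05)
})

test_that("doubling the sampling density changes the area estimate by < 2 percent", {
  a1 <- leaf_area(sample_rectangle(spacing = 0.8, seed = 44))
  a2 <- leaf_area(sample_rectangle(spacing = 0.8 / sqrt(2), seed = 45))
  expect_lt(abs(a2 - a1) / a1, 0.02)
})
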