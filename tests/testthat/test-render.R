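test_that("z-buffer rendering keeps the nearest point and marks coverage", {
  v <- test_camera()
  d <- render_depth(v, point_cloud(matrix(c(0, 0, 500), 1)), splat_radius_px = 0)
  expect_equal(n_valid(d), 1)
  expect_equal(d$values[51, 51], 500) # principal point, 0-based (50, 50)
  # two points on the same ray: nearest wins
  d2 <- render_depth(v, point_cloud(rbind(c(0, 0, 500), c(0, 0, 600))), 0)
  expect_equal(d2$values[51, 51], 500)
  # splat radius 1 covers a 3x3 footprint
  d3 <- render_depth(v, point_cloud(matrix(c(0, 0, 500), 1)), 1)
  expect_equal(n_valid(d3), 9)
  expect_error(render_depth(v, point_cloud(matrix(c(0, 0, 500), 1)), -1), ">= 0")
  # empty cloud: all invalid
  expect_equal(n_valid(render_depth(v, point_cloud(NULL))), 0)
})

test_that("rendering a dense plane reproduces analytic plane depth", {
  v <- test_camera()
  # plane z = 500 tilted: z = 500 + 0.2 * x, sampled densely
  g <- expand.grid(x = seq(-30, 30, by = 0.4), y = seq(-30, 30, by = 0.4))
  cloud <- point_cloud(cbind(g$x, g$y, 500 + 0.2 * g$x))
  d <- render_depth(v, cloud, splat_radius_px = 1)
  sel <- which(d$mask, arr.ind = TRUE)
  px <- sel[, 2] - 1; py <- sel[, 1] - 1
  # analytic depth along the pixel ray: x = (px-cx)/f * z, z = 500 + 0.2 x
  xr <- (px - 50) / 100
  analytic <- 500 / (1 - 0.2 * xr)
  err <- abs(d$values[sel] - analytic)
  # bound: lateral quantization (1.5 px splat ~ depth * 1.5 / f mm) times the
  # plane slope, plus the sampling spacing
  bound <- max(analytic) * 1.5 / 100 * 0.2 + 0.4
  expect_lt(max(err), bound)
})

test_that("rendering is equivariant under rigid world transforms", {
  sc <- small_scene()
  v <- sc$views[[3]]
  tf <- rigid_transform(rotation_about(c(0.3, 1, 0.5), 33), c(25, -40, 60))
  # camera E compensated by T^-1: E' = E %*% T^-1 as 4x4
  T4 <- rbind(cbind(tf$rotation, tf$translation), c(0, 0, 0, 1))
  E2 <- v$extrinsic %*% solve(T4)
  # re-orthonormalize against numerical drift before the class check
  R2 <- E2[1:3, 1:3]; s <- svd(R2); E2[1:3, 1:3] <- s$u %*% t(s$v)
  v2 <- camera_view(v$intrinsic, E2, v$width, v$height,
                    v$depth_min, v$depth_interval)
  cl2 <- transform_points(sc$cloud, tf)
  d1 <- render_depth(v, sc$cloud, 0)
  d2 <- render_depth(v2, cl2, 0)
  expect_equal(d1$mask, d2$mask)
  expect_equal(d1$values, d2$values, tolerance = 1e-9)
})

test_that("rendered depth maps satisfy the depth-map invariants", {
  sc <- small_scene()
  for (d in sc$gt[c(1, 4)]) {
    expect_true(all(is.finite(d$values)))
    expect_true(all(d$values >= 0))
    expect_identical(d$mask, d$values > 0)
  }
})

test_that("pinhole filling closes isolated holes but not silhouettes", {
  v <- test_camera()
  g <- expand.grid(x = seq(-20, 20, by = 0.4), y = seq(-20, 20, by = 0.4))
  cloud <- point_cloud(cbind(g$x, g$y, 500))
  d <- render_depth(v, cloud, 0)
  holed <- d$values
  holed[51, 51] <- 0 # punch one interior pinhole at the patch centre
  filled <- fill_depth_pinholes(depth_map(holed, view = v))
  expect_equal(filled$values[51, 51], 500, tolerance = 1e-9)
  # silhouette stays: background far from the patch is untouched
  expect_equal(sum(filled$mask), sum(d$mask))
})

test_that("visible_points separates front surfaces from occluded ones", {
  v <- test_camera()
  front <- cbind(seq(-10, 10, 0.4), 0, 500)
  behind <- cbind(seq(-10, 10, 0.4), 0, 600) # hidden behind the front strip
  cloud <- point_cloud(rbind(front, behind))
  dm <- render_depth(v, cloud, 1)
  vis <- visible_points(cloud, list(dm), tol_mm = 1)
  expect_true(all(vis[seq_len(nrow(front))]))
  expect_false(any(vis[nrow(front) + seq_len(nrow(behind))]))
})
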