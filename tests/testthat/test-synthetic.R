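test_that("scene specs validate ring coverage and degenerate inputs", {
  expect_s3_class(scene_spec(), "scene_spec")
  expect_error(scene_spec(n_views = 48, angular_step = 10), "360")
  expect_error(scene_spec(n_views = 7, heights = c(200, 360)), "evenly")
  expect_error(scene_spec(plant_height = 0), "positive")
})

test_that("the sampled cloud is reproducible and lies on the analytic surface", {
  spec <- small_scene_spec()
  a <- make_plant_cloud(spec)
  b <- make_plant_cloud(spec)
  expect_identical(a$cloud$points, b$cloud$points)
  res <- a$surface$distance_bound(a$cloud$points)
  expect_lt(max(res), 1e-9)
})

test_that("the generated plant realizes the specified height", {
  spec <- small_scene_spec()
  cloud <- make_plant_cloud(spec)$cloud
  expect_equal(plant_height(cloud), spec$plant_height, tolerance = 1e-9)
})

test_that("the camera ring covers the azimuths at the stated step and sees the plant", {
  spec <- scene_spec(seed = 2) # default: 48 views, 15 deg, two rings
  views <- make_camera_ring(spec)
  expect_length(views, 48)
  centers <- t(vapply(views, camera_center, numeric(3)))
  ring1 <- centers[1:24, ]; ring2 <- centers[25:48, ]
  expect_equal(unique(round(ring1[, 3], 9)), spec$heights[1])
  expect_equal(unique(round(ring2[, 3], 9)), spec$heights[2])
  az <- sort(round(atan2(ring1[, 2], ring1[, 1]) * 180 / pi %% 360, 6)) %% 360
  expect_equal(sort(az %% 360), seq(0, 345, by = 15), tolerance = 1e-6)
  # consecutive same-ring cameras subtend 15 degrees at the plant axis
  v1 <- ring1[1, 1:2]; v2 <- ring1[2, 1:2]
  ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  expect_equal(ang, 15, tolerance = 1e-9)
  # every camera images the centroid well inside the frame
  target <- c(0, 0, spec$plant_height / 2)
  for (v in views[seq(1, 48, by = 7)]) {
    pr <- project(v, matrix(target, 1))
    expect_false(pr$behind)
    expect_true(all(pr$pixels > 0.25 * c(v$width, v$height) &
                    pr$pixels < 0.75 * c(v$width, v$height)))
  }
})

test_that("noise-free scenes close the loop: predictions equal ground truth", {
  sc <- small_scene()
  expect_identical(sc$pred[[1]]$values, sc$gt[[1]]$values)
  expect_equal(mae_depth(sc$gt[[1]], sc$pred[[1]]), 0)
})

test_that("scene files on disk are byte-identical across runs of the same seed", {
  spec <- small_scene_spec(seed = 6)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  make_scene(spec, d1)
  make_scene(spec, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_true(length(f1) >= 5 * spec$n_views + 2)
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f1))
  expect_identical(unname(h1), unname(h2))
})

test_that("scenes read back from disk support fusion and evaluation", {
  spec <- small_scene_spec(seed = 6)
  dir <- withr::local_tempdir()
  make_scene(spec, dir)
  sc <- read_scene(dir)
  expect_length(sc$views, spec$n_views)
  expect_s3_class(sc$views[[1]]$depth, "depth_map")
  expect_s3_class(sc$gt_cloud, "point_cloud")
  fused <- fuse_depth_maps(sc$views, consistency_params(
    min_consistent_views = 3, num_source_views = 7))
  expect_gt(n_points(fused), 500)
  # d_th matched to this fixture's ~2 mm pixel footprint
  rep <- evaluate_clouds(fused, sc$gt_cloud, d_th = 2)
  expect_gt(rep$acc, 90)
})

test_that("depth noise lands where it is asked to", {
  sc_noise <- small_scene(seed = 12, noise_sigma = 1)
  gt <- sc_noise$gt[[1]]; pred <- sc_noise$pred[[1]]
  expect_identical(gt$mask, pred$mask)
  expect_gt(mae_depth(gt, pred), 0.5)
  # edge-localized corruption raises error near depth edges only
  sc_edge <- small_scene(seed = 12, edge_noise_sigma = 5)
  g <- sc_edge$gt[[2]]; p <- sc_edge$pred[[2]]
  em <- depth_edge_mask(g)
  if (any(em$values)) {
    d2e <- leafmvs:::cpp_edt(!em$values)
    band <- g$mask & d2e <= sc_edge$spec$edge_band_px
    far <- g$mask & d2e > 3 * sc_edge$spec$edge_band_px
    if (sum(band) > 50 && sum(far) > 50) {
      expect_gt(mae_depth(g, p, region_mask = band),
                mae_depth(g, p, region_mask = far))
    }
  }
})
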