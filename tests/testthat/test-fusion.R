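test_that("plant-mask filtering intersects the valid set", {
  sc <- small_scene()
  d <- sc$gt[[1]]
  all_true <- matrix(TRUE, nrow(d$values), ncol(d$values))
  expect_equal(filter_plant_mask(d, all_true)$values, d$values)
  expect_equal(n_valid(filter_plant_mask(d, !all_true)), 0)
  set.seed(10)
  rnd <- matrix(runif(length(d$values)) < 0.5, nrow(d$values))
  expect_equal(n_valid(filter_plant_mask(d, rnd)), sum(d$mask & rnd))
})

test_that("exact renders of one surface are geometrically consistent", {
  # adjacent 15-degree views at a resolution where the splat quantization of
  # the rendered maps stays inside the < 1 px round-trip budget for most
  # pixels (nearest-pixel source lookups make a residual fraction miss it)
  spec <- scene_spec(n_leaves = 4, leaf_size = 50, plant_height = 100,
                     n_views = 24, heights = 280, angular_step = 15,
                     image_width = 192, image_height = 192, focal_px = 470,
                     point_spacing = 0.8, seed = 6)
  pc <- make_plant_cloud(spec)
  views <- make_camera_ring(spec)
  ref <- fill_depth_pinholes(render_depth(views[[1]], pc$cloud, 0))
  src <- fill_depth_pinholes(render_depth(views[[2]], pc$cloud, 0))
  valid <- which(ref$mask)
  H <- nrow(ref$values)
  pixels <- cbind((valid - 1) %/% H, (valid - 1) %% H)
  res <- check_consistency(ref, src, pixels)
  # co-visible pixels: those whose reprojection landed on a valid source pixel
  covis <- is.finite(res$reproj_px)
  expect_gt(mean(covis), 0.9)
  expect_gt(mean(res$consistent[covis]), 0.8)
  expect_true(all(abs(res$d_reproj[res$consistent] -
                      ref$values[valid][res$consistent]) /
                  ref$values[valid][res$consistent] < 0.01))
})

test_that("a 2 percent depth perturbation violates the 1 percent gate", {
  sc <- small_scene()
  ref <- sc$gt[[1]]; src <- sc$gt[[2]]
  valid <- which(ref$mask)
  H <- nrow(ref$values)
  # pick a pixel that is cleanly consistent in the unperturbed map
  pixels <- cbind((valid - 1) %/% H, (valid - 1) %% H)
  res0 <- check_consistency(ref, src, pixels)
  good <- which(res0$consistent & res0$rel_depth < 0.003 & res0$reproj_px < 0.3)
  expect_gt(length(good), 0)
  i <- good[1]
  perturbed <- ref$values
  perturbed[valid[i]] <- perturbed[valid[i]] * 1.02
  ref2 <- depth_map(perturbed, view = ref$view)
  res2 <- check_consistency(ref2, src, pixels[i, , drop = FALSE])
  expect_false(res2$consistent[1])
})

test_that("points projecting outside the source image are inconsistent", {
  v1 <- test_camera()
  # source camera rotated 90 degrees about y: looks orthogonally, the scene
  # in front of v1 is far out of its frustum
  R <- rotation_about(c(0, 1, 0), 90)
  v2 <- camera_view(v1$intrinsic, rbind(cbind(R, c(0, 0, 500)), c(0, 0, 0, 1)),
                    100, 100, 400, 2.5)
  ref <- depth_map(matrix(500, 100, 100), view = v1)
  src <- depth_map(matrix(500, 100, 100), view = v2)
  res <- check_consistency(ref, src, c(50, 50))
  expect_false(res$consistent[1])
})

test_that("fusing exact renders reproduces the visible surface and respects consensus", {
  sc <- small_scene()
  views <- scene_fusion_views(sc)
  params <- consistency_params(min_consistent_views = 3, num_source_views = 7)
  fused <- fuse_depth_maps(views, params)
  expect_gt(n_points(fused), 1000)
  # fused points lie near the analytic surface or the sampled cloud
  bound <- sc$surface$distance_bound(fused$points)
  nnd <- nn_distances(fused, sc$cloud)
  d <- pmin(bound, nnd)
  # quantization bound: one pixel footprint at the far depth
  px_mm <- (sc$spec$ring_radius + 100) / sc$spec$focal_px
  expect_lt(quantile(d, 0.99), 2 * px_mm)
  prov <- attr(fused, "provenance")
  expect_true(all(prov$n_consistent >= 3))
})

test_that("single or empty view lists cannot be fused", {
  sc <- small_scene()
  expect_error(fuse_depth_maps(list()), "no views")
  expect_warning(f1 <- fuse_depth_maps(scene_fusion_views(sc)[1]), "single view")
  expect_equal(n_points(f1), 0)
})

test_that("fused point count is monotone non-increasing in min_consistent_views", {
  sc <- small_scene()
  views <- scene_fusion_views(sc)
  counts <- vapply(c(0, 2, 4, 6), function(k) {
    n_points(fuse_depth_maps(views, consistency_params(
      min_consistent_views = k, num_source_views = 7)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("fusion output is invariant to the order of the views list", {
  sc <- small_scene()
  views <- scene_fusion_views(sc)
  params <- consistency_params(min_consistent_views = 3, num_source_views = 7)
  f1 <- fuse_depth_maps(views, params)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  f2 <- fuse_depth_maps(views[perm], params)
  expect_equal(n_points(f1), n_points(f2))
  o1 <- f1$points[order(f1$points[, 1], f1$points[, 2], f1$points[, 3]), ]
  o2 <- f2$points[order(f2$points[, 1], f2$points[, 2], f2$points[, 3]), ]
  expect_equal(o1, o2, tolerance = 1e-9)
})

test_that("consistency parameter validation", {
  expect_error(consistency_params(min_consistent_views = 11,
                                  num_source_views = 10), "exceed")
  expect_error(consistency_params(max_reproj_px = 0), "positive")
  expect_error(consistency_params(max_rel_depth = -0.01), "positive")
})
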