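# Shared fixtures. Small scenes are cached per test run (building them is the
# expensive part of the suite).

test_camera <- function(f = 100, c = 50, size = 100, extrinsic = diag(4),
                        depth_min = 400, depth_interval = 2.5) {
  camera_view(matrix(c(f, 0, 0, 0, f, 0, c, c, 1), 3), extrinsic,
              width = size, height = size,
              depth_min = depth_min, depth_interval = depth_interval)
}

# a small but fully functional plant scene: 8 views on one ring, 96 px images
small_scene_spec <- function(seed = 5, ...) {
  scene_spec(n_leaves = 3, leaf_size = 40, plant_height = 90,
             n_views = 8, heights = 250, angular_step = 45,
             image_width = 96, image_height = 96, focal_px = 235,
             point_spacing = 1.6, seed = seed, ...)
}

.scene_cache <- new.env(parent = emptyenv())

cached_scene <- function(key, builder) {
  if (is.null(.scene_cache[[key]])) .scene_cache[[key]] <- builder()
  .scene_cache[[key]]
}

small_scene <- function(seed = 5, ...) {
  key <- paste0("small_", seed, "_", paste(c(...), collapse = "_"))
  cached_scene(key, function() make_scene(small_scene_spec(seed = seed, ...)))
}

scene_fusion_views <- function(sc) {
  lapply(seq_along(sc$views), function(i)
    list(depth = sc$pred[[i]], plant_mask = sc$masks[[i]]))
}

# random rotation about a given axis/angle (degrees)
rotation_about <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K
}
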