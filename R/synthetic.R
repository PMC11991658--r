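#' Specification of a synthetic plant scene
#'
#' Describes a plant-like test scene: a stem with paraboloid leaf lobes whose
#' rims ripple (giving genuine depth discontinuities at leaf edges), imaged
#' from a two-height camera ring — 15 degree steps and 48 poses by default,
#' mirroring a turntable acquisition rig. All randomness (leaf layout, point
#' sampling jitter, depth noise) derives from `seed`, with one RNG stream per
#' artifact type so that, e.g., enabling noise does not change the sampled
#' cloud.
#'
#' The imaging geometry defaults (512 x 512 px, 1250 px focal length, 500 mm
#' ring radius) give a ~0.4 mm pixel footprint at the plant — the regime in
#' which a 0.4 mm point-cloud accuracy threshold is meaningful — and the
#' default cloud sampling (0.35 mm) is denser than that footprint so each
#' pixel sees at least one surface point.
#'
#' @param n_leaves number of leaves.
#' @param leaf_size nominal leaf length, millimetres.
#' @param plant_height stem height (= total plant height), millimetres.
#' @param n_views total number of camera poses.
#' @param ring_radius camera ring radius, millimetres.
#' @param heights ring elevations, millimetres (one ring per element).
#' @param angular_step azimuth step within a ring, degrees;
#'   `n_views / length(heights) * angular_step` must be 360.
#' @param noise_sigma Gaussian depth noise applied to the "predicted" depth
#'   maps, millimetres (0 = predictions equal ground truth).
#' @param edge_noise_sigma extra noise applied within `edge_band_px` of
#'   depth edges, millimetres (exercises edge metrics).
#' @param edge_band_px width of the edge-corruption band, pixels.
#' @param seed master seed for all randomness.
#' @param image_width,image_height image size, pixels.
#' @param focal_px focal length, pixels.
#' @param point_spacing ground-truth cloud sampling distance, millimetres.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(n_leaves = 6, leaf_size = 60, plant_height = 120,
                       n_views = 48, ring_radius = 500,
                       heights = c(200, 360), angular_step = 15,
                       noise_sigma = 0, edge_noise_sigma = 0,
                       edge_band_px = 4, seed = 1,
                       image_width = 512, image_height = 512,
                       focal_px = 1250, point_spacing = 0.35) {
  if (n_leaves < 0 || plant_height <= 0)
    stop("need a positive plant height (and a non-negative leaf count)")
  if (n_leaves == 0 && plant_height == 0) stop("degenerate scene spec")
  n_rings <- length(heights)
  if (n_views %% n_rings != 0)
    stop("n_views must divide evenly over the rings")
  if (abs((n_views / n_rings) * angular_step - 360) > 1e-9)
    stop("n_views/rings * angular_step must equal 360 degrees of coverage")
  structure(list(n_leaves = as.integer(n_leaves), leaf_size = leaf_size,
                 plant_height = plant_height, n_views = as.integer(n_views),
                 ring_radius = ring_radius, heights = heights,
                 angular_step = angular_step, noise_sigma = noise_sigma,
                 edge_noise_sigma = edge_noise_sigma,
                 edge_band_px = edge_band_px, seed = as.integer(seed),
                 image_width = as.integer(image_width),
                 image_height = as.integer(image_height),
                 focal_px = focal_px, point_spacing = point_spacing),
            class = "scene_spec")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

STEM_RADIUS <- 3   # mm
LEAF_RIPPLE <- 0.12 # fractional rim indentation depth
LEAF_RIPPLE_N <- 7  # ripple lobes around the rim

# Deterministic leaf layout drawn from the cloud RNG stream.
leaf_params <- function(spec) {
  if (spec$n_leaves == 0) return(list())
  H <- spec$plant_height
  lapply(seq_len(spec$n_leaves), function(i) {
    phi <- 2 * pi * (i - 1) / spec$n_leaves + runif(1, -0.2, 0.2)
    z0 <- H * runif(1, 0.30, 0.65)
    L <- spec$leaf_size * runif(1, 0.8, 1.2)
    W <- 0.35 * L
    a <- 0.12 * L # paraboloid curl depth
    tilt <- runif(1, 20, 40) * pi / 180
    # keep the leaf tip below the stem top so the stem defines plant height
    max_rise <- 0.95 * H - z0 - a
    if (L * sin(tilt) > max_rise)
      tilt <- asin(pmax(0.05, max_rise) / L)
    phase <- runif(1, 0, 2 * pi)
    e_s <- c(cos(phi) * cos(tilt), sin(phi) * cos(tilt), sin(tilt))
    e_t <- c(-sin(phi), cos(phi), 0)
    e_n <- cross3(e_s, e_t)
    if (e_n[3] < 0) e_n <- -e_n
    list(origin = c(STEM_RADIUS * cos(phi), STEM_RADIUS * sin(phi), z0),
         e_s = e_s, e_t = e_t, e_n = e_n,
         L = L, W = W, a = a, phase = phase)
  })
}

# Rippled elliptical domain test in normalized leaf coordinates.
# su = (s - L/2) / (L/2), tv = t / W; returns TRUE inside the rim.
leaf_in_domain <- function(su, tv, phase) {
  r <- sqrt(su^2 + tv^2)
  th <- atan2(tv, su)
  rim <- 1 - LEAF_RIPPLE * (0.5 + 0.5 * sin(LEAF_RIPPLE_N * th + phase))
  r <= rim
}

leaf_height <- function(leaf, s, t) {
  su <- (s - leaf$L / 2) / (leaf$L / 2)
  tv <- t / leaf$W
  leaf$a * (su^2 + tv^2)
}

#' Sample a synthetic plant point cloud
#'
#' Builds the ground-truth plant surface — a vertical stem cylinder spanning
#' exactly `[0, plant_height]` plus paraboloid leaf patches with rippled rims
#' — and samples it on a jittered grid at `point_spacing`. Returns both the
#' sampled cloud and an analytic surface handle for test assertions: the
#' handle evaluates, for arbitrary query points, an upper bound on the
#' distance to the surface (the normal-direction residual for queries over a
#' leaf's domain; the radial residual for queries beside the stem), and the
#' exact residual is ~0 for the sampled points by construction. Fully
#' reproducible from `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @return A list with `cloud` (a colored [point_cloud()]) and `surface`
#'   (the handle: fields `parts` and function `distance_bound(points)`).
#' @export
make_plant_cloud <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed) # cloud stream
  leaves <- leaf_params(spec)
  h <- spec$point_spacing
  pts <- list()

  # stem: cylinder, rows at exact z = 0 and z = plant_height included
  nz <- max(2L, ceiling(spec$plant_height / h) + 1L)
  zs <- seq(0, spec$plant_height, length.out = nz)
  na <- max(6L, ceiling(2 * pi * STEM_RADIUS / h))
  ang <- seq(0, 2 * pi, length.out = na + 1)[-(na + 1)]
  g <- expand.grid(z = zs, ang = ang)
  pts$stem <- cbind(STEM_RADIUS * cos(g$ang), STEM_RADIUS * sin(g$ang), g$z)

  for (leaf in leaves) {
    # jittered grid over the (s, t) parameter plane; grid step shrunk a bit
    # so the sampled world spacing stays <= point_spacing on slopes
    step <- 0.9 * h
    ss <- seq(0, leaf$L, by = step)
    ts <- seq(-leaf$W, leaf$W, by = step)
    g <- expand.grid(s = ss, t = ts)
    g$s <- g$s + runif(nrow(g), -0.3, 0.3) * step
    g$t <- g$t + runif(nrow(g), -0.3, 0.3) * step
    su <- (g$s - leaf$L / 2) / (leaf$L / 2)
    tv <- g$t / leaf$W
    keep <- leaf_in_domain(su, tv, leaf$phase)
    g <- g[keep, , drop = FALSE]
    hgt <- leaf_height(leaf, g$s, g$t)
    P <- outer(g$s, leaf$e_s) + outer(g$t, leaf$e_t) + outer(hgt, leaf$e_n)
    pts[[length(pts) + 1]] <- sweep(P, 2, -leaf$origin)
  }
  all_pts <- do.call(rbind, pts)
  # green shading by height for visual inspection of exported PLY
  gshade <- 120 + 100 * (all_pts[, 3] / spec$plant_height)
  colors <- cbind(0.3 * gshade, gshade, 0.3 * gshade)
  colors <- pmin(pmax(colors, 0), 255)

  surface <- list(
    parts = c(list(list(type = "stem", radius = STEM_RADIUS,
                        z_range = c(0, spec$plant_height))),
              lapply(leaves, function(l) c(list(type = "leaf"), l))),
    distance_bound = function(points) {
      points <- as_points_matrix(points)
      best <- rep(Inf, nrow(points))
      r <- sqrt(points[, 1]^2 + points[, 2]^2)
      inz <- points[, 3] >= 0 & points[, 3] <= spec$plant_height
      best[inz] <- abs(r[inz] - STEM_RADIUS)
      for (leaf in leaves) {
        Q <- sweep(points, 2, leaf$origin)
        s <- as.numeric(Q %*% leaf$e_s)
        t <- as.numeric(Q %*% leaf$e_t)
        n <- as.numeric(Q %*% leaf$e_n)
        su <- (s - leaf$L / 2) / (leaf$L / 2)
        tv <- t / leaf$W
        ind <- leaf_in_domain(su, tv, leaf$phase)
        res <- abs(n - leaf$a * (su^2 + tv^2))
        best[ind] <- pmin(best[ind], res[ind])
      }
      best
    })
  list(cloud = point_cloud(all_pts, colors), surface = surface)
}

#' Build the two-height camera ring of a scene
#'
#' Cameras sit on circles of radius `ring_radius` at the requested heights,
#' at `angular_step` azimuth intervals, all looking at the plant centroid
#' (stem axis at half height). Intrinsics are shared; extrinsics are exact
#' world-to-camera transforms.
#'
#' @param spec a [scene_spec()].
#' @return List of [camera_view()]s of length `spec$n_views`, ring by ring.
#' @export
make_camera_ring <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  target <- c(0, 0, spec$plant_height / 2)
  n_per <- spec$n_views / length(spec$heights)
  K <- matrix(c(spec$focal_px, 0, 0,
                0, spec$focal_px, 0,
                (spec$image_width - 1) / 2, (spec$image_height - 1) / 2, 1), 3)
  views <- list()
  for (hz in spec$heights) {
    for (j in seq_len(n_per)) {
      az <- (j - 1) * spec$angular_step * pi / 180
      C <- c(spec$ring_radius * cos(az), spec$ring_radius * sin(az), hz)
      zc <- target - C; zc <- zc / sqrt(sum(zc^2))
      xc <- cross3(zc, c(0, 0, 1))
      xc <- xc / sqrt(sum(xc^2))
      yc <- cross3(zc, xc)
      R <- rbind(xc, yc, zc)
      tvec <- -as.numeric(R %*% C)
      E <- rbind(cbind(R, tvec), c(0, 0, 0, 1))
      dist <- sqrt(sum((C - target)^2))
      v <- camera_view(K, E, spec$image_width, spec$image_height,
                       depth_min = dist - 160, depth_interval = 320 / 191)
      attr(v, "depth_extra") <- c(192, dist + 160)
      views[[length(views) + 1]] <- v
    }
  }
  views
}

#' Generate a full synthetic scene on disk
#'
#' Renders a ground-truth depth map per camera (z-buffer splatting of the
#' sampled plant cloud, splat radius 0 since the cloud is denser than the
#' pixel grid), derives plant masks from depth validity, fabricates
#' "predicted" depth maps as ground truth plus seeded Gaussian noise
#' (`noise_sigma`, with optional extra corruption within `edge_band_px` of
#' depth edges to exercise edge metrics), and writes the MVS scene layout:
#' `images/%08d.png`, `cams/%08d_cam.txt`, `depths/%08d.pfm` (predicted),
#' `gt_depths/%08d.pfm`, `masks/%08d.png`, `cloud.ply` (ground-truth cloud)
#' and `scene.yaml`. Two runs with the same spec produce identical files.
#'
#' @param spec a [scene_spec()].
#' @param out_dir output directory (created if missing). `NULL` keeps the
#'   scene in memory only.
#' @return Invisibly, a list with `spec`, `dir`, `cloud`, `surface`, `views`,
#'   and per-view lists `gt`, `pred`, `masks`, `images`.
#' @export
make_scene <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  pc <- make_plant_cloud(spec)
  views <- make_camera_ring(spec)
  nv <- length(views)
  gt <- vector("list", nv); pred <- vector("list", nv)
  masks <- vector("list", nv); images <- vector("list", nv)
  set.seed(spec$seed + 131071L) # noise stream, independent of cloud sampling
  for (i in seq_len(nv)) {
    g <- render_depth(views[[i]], pc$cloud, splat_radius_px = 0)
    g <- fill_depth_pinholes(g)
    gt[[i]] <- g
    masks[[i]] <- g$mask
    v <- g$values
    if (spec$noise_sigma > 0)
      v[g$mask] <- v[g$mask] + rnorm(sum(g$mask), 0, spec$noise_sigma)
    if (spec$edge_noise_sigma > 0 && any(g$mask)) {
      em <- depth_edge_mask(g)
      band <- matrix(FALSE, nrow(v), ncol(v))
      if (any(em$values)) {
        d2e <- cpp_edt(!em$values) # distance to nearest depth-edge pixel
        band <- g$mask & d2e <= spec$edge_band_px
      }
      if (any(band))
        v[band] <- v[band] + rnorm(sum(band), 0, spec$edge_noise_sigma)
    }
    v[g$mask] <- pmax(v[g$mask], 1e-3) # keep noisy pixels valid
    pred[[i]] <- depth_map(v, view = views[[i]])
    # shaded RGB proxy: brightness from inverse depth over the valid range
    img <- array(0, c(nrow(v), ncol(v), 3))
    if (any(g$mask)) {
      rng <- range(g$values[g$mask])
      shade <- matrix(0, nrow(v), ncol(v))
      den <- max(rng[2] - rng[1], 1e-9)
      shade[g$mask] <- 0.35 + 0.6 * (rng[2] - g$values[g$mask]) / den
      img[, , 1] <- 0.3 * shade
      img[, , 2] <- shade
      img[, , 3] <- 0.3 * shade
    }
    images[[i]] <- img * 255
  }
  scene <- list(spec = spec, dir = out_dir, cloud = pc$cloud,
                surface = pc$surface, views = views, gt = gt, pred = pred,
                masks = masks, images = images)
  if (!is.null(out_dir)) {
    for (sub in c("images", "cams", "depths", "gt_depths", "masks"))
      dir.create(file.path(out_dir, sub), recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nv)) {
      tag <- sprintf("%08d", i - 1)
      write_image(images[[i]], file.path(out_dir, "images", paste0(tag, ".png")))
      write_cam_txt(views[[i]], file.path(out_dir, "cams", paste0(tag, "_cam.txt")))
      write_pfm(pred[[i]], file.path(out_dir, "depths", paste0(tag, ".pfm")))
      write_pfm(gt[[i]], file.path(out_dir, "gt_depths", paste0(tag, ".pfm")))
      write_image(masks[[i]] * 1, file.path(out_dir, "masks", paste0(tag, ".png")))
    }
    write_ply(pc$cloud, file.path(out_dir, "cloud.ply"))
    yaml::write_yaml(unclass(spec), file.path(out_dir, "scene.yaml"))
  }
  invisible(scene)
}

#' Load a scene directory into fusion-ready structures
#'
#' Reads `scene.yaml`, cameras, predicted depth maps, masks and images from a
#' directory written by [make_scene()] (or following the same layout).
#'
#' @param dir scene directory.
#' @return A list with `spec` (when scene.yaml is present), `views` (fusion
#'   input: per-view `depth`, `plant_mask`, `image`) and `gt_cloud` (when
#'   cloud.ply is present).
#' @export
read_scene <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("scene directory not found: %s", dir))
  spec <- NULL
  yml <- file.path(dir, "scene.yaml")
  if (file.exists(yml)) spec <- do.call(scene_spec, yaml::read_yaml(yml))
  depth_files <- sort(list.files(file.path(dir, "depths"), "\\.pfm$",
                                 full.names = TRUE))
  if (length(depth_files) == 0) stop(sprintf("no depth maps under %s/depths", dir))
  views <- lapply(depth_files, function(f) {
    tag <- sub("\\.pfm$", "", basename(f))
    d0 <- read_pfm(f)
    cam_f <- file.path(dir, "cams", paste0(tag, "_cam.txt"))
    if (!file.exists(cam_f)) stop(sprintf("missing camera file: %s", cam_f))
    cam <- read_cam_txt(cam_f, width = ncol(d0$values), height = nrow(d0$values))
    v <- list(depth = depth_map(d0$values, view = cam))
    mask_f <- file.path(dir, "masks", paste0(tag, ".png"))
    if (file.exists(mask_f)) v$plant_mask <- read_image(mask_f) > 127
    img_f <- file.path(dir, "images", paste0(tag, ".png"))
    if (file.exists(img_f)) v$image <- read_image(img_f)
    v
  })
  out <- list(spec = spec, views = views)
  ply <- file.path(dir, "cloud.ply")
  if (file.exists(ply)) out$gt_cloud <- read_ply(ply)
  out
}
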