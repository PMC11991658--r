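#' Render a ground-truth depth map from a point cloud
#'
#' Z-buffer point splatting: every cloud point in front of the camera is
#' projected, rounded to its nearest pixel, and splatted over a
#' `(2r+1) x (2r+1)` footprint; each covered pixel keeps the minimum depth
#' (nearest surface wins). Pixels covered by no point are invalid. This is how
#' ground-truth depth maps are produced from a reference (scanner-grade) cloud
#' whose density exceeds the pixel footprint.
#'
#' @param view a [camera_view()].
#' @param cloud a [point_cloud()]; an empty cloud yields an all-invalid map.
#' @param splat_radius_px non-negative integer footprint radius. The default 1
#'   closes pinholes left by scanner-density clouds; use 0 for clouds already
#'   denser than the pixel grid.
#' @return A [depth_map()] attached to `view`.
#' @export
render_depth <- function(view, cloud, splat_radius_px = 1) {
  stopifnot(inherits(view, "camera_view"), inherits(cloud, "point_cloud"))
  if (!(splat_radius_px >= 0)) stop("splat_radius_px must be >= 0")
  H <- view$height; W <- view$width
  values <- matrix(0, H, W)
  if (n_points(cloud) == 0) return(depth_map(values, view = view))

  pr <- project(view, cloud$points)
  keep <- !pr$behind
  px <- round(pr$pixels[keep, 1])
  py <- round(pr$pixels[keep, 2])
  z <- pr$depths[keep]
  r <- as.integer(splat_radius_px)
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  n <- length(z)
  if (n == 0) return(depth_map(values, view = view))

  tx <- rep(px, times = nrow(offs)) + rep(offs$dx, each = n)
  ty <- rep(py, times = nrow(offs)) + rep(offs$dy, each = n)
  tz <- rep(z, times = nrow(offs))
  inb <- tx >= 0 & tx < W & ty >= 0 & ty < H
  tx <- tx[inb]; ty <- ty[inb]; tz <- tz[inb]
  if (length(tz) == 0) return(depth_map(values, view = view))

  lin <- ty * W + tx # 0-based linear pixel id
  o <- order(lin, tz)
  lin <- lin[o]; tz <- tz[o]
  first <- !duplicated(lin) # minimum depth per pixel after the sort
  lin <- lin[first]; tz <- tz[first]
  # values is H x W, R column-major: element (row y+1, col x+1) = y + 1 + x*H
  values[(lin %% W) * H + (lin %/% W) + 1] <- tz
  depth_map(values, view = view)
}

#' Fill isolated pinholes in a rendered depth map
#'
#' Z-buffer splatting of a sampled cloud can leave isolated invalid pixels
#' inside otherwise covered surface regions. An invalid pixel with at least
#' `min_neighbors` valid 8-neighbours is filled with their mean depth;
#' genuine background (straight silhouette borders have at most ~5 valid
#' neighbours) is left untouched.
#'
#' @param depth a [depth_map()].
#' @param min_neighbors required number of valid neighbours (default 6).
#' @param iterations how many filling passes to run.
#' @return A [depth_map()] with pinholes filled.
#' @export
fill_depth_pinholes <- function(depth, min_neighbors = 6, iterations = 1) {
  stopifnot(inherits(depth, "depth_map"))
  v <- depth$values
  for (it in seq_len(iterations)) {
    mask <- v > 0
    acc <- matrix(0, nrow(v), ncol(v))
    cnt <- matrix(0, nrow(v), ncol(v))
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      acc <- acc + shift_mat(v, dy, dx)
      cnt <- cnt + shift_mat(mask, dy, dx, fill = FALSE)
    }
    fill <- !mask & cnt >= min_neighbors
    if (!any(fill)) break
    v[fill] <- acc[fill] / cnt[fill]
  }
  depth_map(v, view = depth$view)
}

#' Which cloud points are visible from a set of views
#'
#' A point counts as visible when, in at least one view, it projects into the
#' image and its depth is within `tol_mm` of that view's depth map at the
#' pixel it lands on. With depth maps rendered from the cloud itself this
#' identifies the subset that survives z-buffer occlusion — the part of a
#' ground-truth cloud a multi-view reconstruction can be expected to recover
#' (inner stems and under-leaf surfaces occluded in every view cannot).
#'
#' @param cloud a [point_cloud()].
#' @param depth_maps list of [depth_map()]s with attached views.
#' @param tol_mm depth agreement tolerance, millimetres.
#' @return Logical vector over the cloud's points.
#' @export
visible_points <- function(cloud, depth_maps, tol_mm = 1) {
  stopifnot(inherits(cloud, "point_cloud"))
  vis <- rep(FALSE, n_points(cloud))
  if (n_points(cloud) == 0) return(vis)
  for (dm in depth_maps) {
    stopifnot(inherits(dm, "depth_map"))
    if (is.null(dm$view)) stop("depth maps must carry their camera views")
    todo <- which(!vis)
    if (length(todo) == 0) break
    pr <- project(dm$view, cloud$points[todo, , drop = FALSE])
    px <- round(pr$pixels[, 1]); py <- round(pr$pixels[, 2])
    inb <- !pr$behind & px >= 0 & px < dm$view$width &
      py >= 0 & py < dm$view$height
    if (!any(inb)) next
    lin <- py[inb] + 1 + px[inb] * nrow(dm$values)
    dv <- dm$values[lin]
    hit <- dv > 0 & abs(dv - pr$depths[inb]) < tol_mm
    vis[todo[inb][hit]] <- TRUE
  }
  vis
}
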