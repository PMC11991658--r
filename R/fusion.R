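#' Geometric-consistency parameters for depth-map fusion
#'
#' A reference-pixel depth estimate is accepted only when enough neighbouring
#' source views confirm it: the reference pixel is lifted to 3D, looked up in
#' the source depth map, reprojected back, and must land within
#' `max_reproj_px` pixels of where it started with a relative depth
#' disagreement below `max_rel_depth` (both strict inequalities, as is
#' conventional: < 1 px and < 1%).
#'
#' @param max_reproj_px reprojection distance threshold, pixels (default 1).
#' @param max_rel_depth relative depth threshold, fraction (default 0.01).
#' @param min_consistent_views how many source views must agree before a
#'   pixel emits a point (default 4). 0 disables the gate (every valid pixel
#'   emits a point, averaging whatever sources happen to agree).
#' @param num_source_views how many neighbouring views are checked
#'   (default 10).
#' @return An object of class `consistency_params`.
#' @export
consistency_params <- function(max_reproj_px = 1, max_rel_depth = 0.01,
                               min_consistent_views = 4,
                               num_source_views = 10) {
  if (!(max_reproj_px > 0 && max_rel_depth > 0 && num_source_views > 0))
    stop("thresholds and view counts must be strictly positive")
  if (min_consistent_views < 0) stop("min_consistent_views must be >= 0")
  if (min_consistent_views > num_source_views)
    stop("min_consistent_views cannot exceed num_source_views")
  structure(list(max_reproj_px = max_reproj_px, max_rel_depth = max_rel_depth,
                 min_consistent_views = as.integer(min_consistent_views),
                 num_source_views = as.integer(num_source_views)),
            class = "consistency_params")
}

#' Restrict a depth map to a plant mask
#'
#' Background depth estimates are unreliable and poison fusion; this keeps
#' only pixels flagged as plant, zeroing (invalidating) the rest.
#'
#' @param depth a [depth_map()].
#' @param plant_mask H x W logical matrix.
#' @return A [depth_map()] whose valid set is the intersection.
#' @export
filter_plant_mask <- function(depth, plant_mask) {
  stopifnot(inherits(depth, "depth_map"))
  plant_mask <- as.matrix(plant_mask)
  if (!all(dim(plant_mask) == dim(depth$values)))
    stop("plant mask size does not match the depth map")
  v <- depth$values
  v[!plant_mask] <- 0
  depth_map(v, view = depth$view)
}

# Vectorized consistency check of reference pixels against one source view.
# pixels: m x 2 matrix of 0-based (x, y); depths: reference depths at them.
# Returns list(consistent, d_reproj, reproj_px, rel_depth).
consistency_one_source <- function(ref_view, src, pixels, depths, params) {
  m <- nrow(pixels)
  out <- list(consistent = rep(FALSE, m), d_reproj = rep(NA_real_, m),
              reproj_px = rep(Inf, m), rel_depth = rep(Inf, m))
  X <- backproject(ref_view, pixels, depths)
  ps <- project(src$view, X)
  sx <- round(ps$pixels[, 1]); sy <- round(ps$pixels[, 2])
  inb <- !ps$behind & sx >= 0 & sx < src$view$width &
    sy >= 0 & sy < src$view$height
  if (!any(inb)) return(out)
  lin <- sy[inb] + 1 + sx[inb] * nrow(src$values) # column-major (row=y+1, col=x+1)
  d_src <- src$values[lin]
  ok <- d_src > 0
  if (!any(ok)) return(out)
  sel <- which(inb)[ok]
  X2 <- backproject(src$view, cbind(sx[sel], sy[sel]), d_src[ok])
  pr <- project(ref_view, X2)
  good <- !pr$behind & pr$depths > 0
  reproj <- sqrt((pr$pixels[, 1] - pixels[sel, 1])^2 +
                 (pr$pixels[, 2] - pixels[sel, 2])^2)
  d_rr <- pr$depths
  rel <- abs(depths[sel] - d_rr) / pmax(depths[sel], d_rr)
  out$reproj_px[sel] <- reproj
  out$rel_depth[sel] <- rel
  out$d_reproj[sel] <- d_rr
  out$consistent[sel] <- good & reproj < params$max_reproj_px &
    rel < params$max_rel_depth
  out
}

#' Check geometric consistency of reference pixels against a source view
#'
#' Lifts each reference pixel to 3D with its reference depth, finds the
#' nearest source pixel it lands on, back-projects that source pixel with the
#' source depth, and reprojects into the reference view. The estimate is
#' consistent with the source iff the round trip lands within
#' `max_reproj_px` pixels of the starting pixel and the reference depth and
#' the reprojected source depth differ by less than `max_rel_depth`
#' relatively. Source lookups use nearest-pixel sampling so the sub-pixel
#' reprojection test stays meaningful. Out-of-bounds or invalid source
#' lookups are inconsistent.
#'
#' @param ref a [depth_map()] with an attached view.
#' @param src a [depth_map()] with an attached view.
#' @param pixels m x 2 matrix (or length-2 vector) of 0-based (x, y)
#'   reference pixels, valid in `ref`.
#' @param params a [consistency_params()].
#' @return A data.frame with columns `consistent`, `d_reproj` (the source
#'   depth reprojected into the reference frame, used for averaging),
#'   `reproj_px` and `rel_depth`.
#' @export
check_consistency <- function(ref, src, pixels, params = consistency_params()) {
  stopifnot(inherits(ref, "depth_map"), inherits(src, "depth_map"),
            inherits(params, "consistency_params"))
  if (is.null(ref$view) || is.null(src$view))
    stop("both depth maps must carry their camera views")
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 2)
  pixels <- as.matrix(pixels)
  lin <- pixels[, 2] + 1 + pixels[, 1] * nrow(ref$values)
  depths <- ref$values[lin]
  if (any(depths <= 0)) stop("all query pixels must be valid in the reference map")
  res <- consistency_one_source(ref$view,
                                list(view = src$view, values = src$values),
                                pixels, depths, params)
  data.frame(consistent = res$consistent, d_reproj = res$d_reproj,
             reproj_px = res$reproj_px, rel_depth = res$rel_depth)
}

#' Fuse per-view depth maps into a point cloud
#'
#' MVSNet-style fusion with geometric averaging. Each view acts in turn as
#' the reference: its plant-masked valid pixels are checked against the
#' `num_source_views` nearest neighbouring views (by camera-centre
#' distance); pixels confirmed by at least `min_consistent_views` sources
#' emit one 3D point whose depth is the mean of the reference depth and all
#' consistent reprojected source depths. Points carry the reference-image
#' color when images are supplied, and a provenance record (reference view,
#' pixel, consistency count) is attached as attribute `"provenance"`.
#'
#' @param views list of views; each element is a list with `depth` (a
#'   [depth_map()] with attached [camera_view()]), optional `plant_mask`
#'   (H x W logical) and optional `image` (H x W x 3 array for coloring).
#' @param params a [consistency_params()].
#' @param ref_views indices of the views to use as references (each emits
#'   points); all views remain available as consistency sources. Default:
#'   every view.
#' @return A [point_cloud()]; empty (with a warning) when no pixel reaches
#'   consensus.
#' @export
fuse_depth_maps <- function(views, params = consistency_params(),
                            ref_views = seq_along(views)) {
  if (length(views) == 0) stop("no views to fuse")
  if (length(views) == 1) {
    warning("single view: consensus impossible, returning empty cloud")
    return(point_cloud(NULL))
  }
  stopifnot(inherits(params, "consistency_params"))
  depths <- lapply(views, function(v) {
    d <- v$depth
    stopifnot(inherits(d, "depth_map"))
    if (is.null(d$view)) stop("every depth map must carry its camera view")
    if (!is.null(v$plant_mask)) d <- filter_plant_mask(d, v$plant_mask)
    d
  })
  centers <- t(vapply(depths, function(d) camera_center(d$view), numeric(3)))
  nv <- length(depths)
  all_pts <- vector("list", nv)
  all_cols <- vector("list", nv)
  all_prov <- vector("list", nv)
  ref_views <- as.integer(ref_views)
  if (any(ref_views < 1 | ref_views > nv)) stop("ref_views out of range")
  for (r in ref_views) {
    ref <- depths[[r]]
    valid <- which(ref$mask)
    if (length(valid) == 0) next
    H <- nrow(ref$values)
    px <- (valid - 1) %/% H       # 0-based x (column)
    py <- (valid - 1) %% H        # 0-based y (row)
    pixels <- cbind(px, py)
    d_ref <- ref$values[valid]
    dd <- sqrt(colSums((t(centers) - centers[r, ])^2))
    dd[r] <- Inf
    src_idx <- order(dd)[seq_len(min(params$num_source_views, nv - 1))]
    n_ok <- integer(length(valid))
    d_sum <- d_ref
    for (s in src_idx) {
      res <- consistency_one_source(ref$view, depths[[s]], pixels, d_ref, params)
      hit <- res$consistent
      n_ok <- n_ok + hit
      d_sum[hit] <- d_sum[hit] + res$d_reproj[hit]
    }
    emit <- n_ok >= params$min_consistent_views
    if (!any(emit)) next
    d_fused <- d_sum[emit] / (n_ok[emit] + 1)
    pts <- backproject(ref$view, pixels[emit, , drop = FALSE], d_fused)
    all_pts[[r]] <- pts
    img <- views[[r]]$image
    if (!is.null(img)) {
      img <- as_image_255(img)
      if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
      li <- valid[emit]
      all_cols[[r]] <- cbind(img[, , 1][li], img[, , 2][li], img[, , 3][li])
    }
    all_prov[[r]] <- data.frame(view = r, x = px[emit], y = py[emit],
                                n_consistent = n_ok[emit], depth = d_fused)
  }
  pts <- do.call(rbind, all_pts)
  if (is.null(pts) || nrow(pts) == 0) {
    warning("no pixels reached geometric consensus; returning empty cloud")
    return(point_cloud(NULL))
  }
  emitted <- !vapply(all_pts, is.null, TRUE)
  col_ok <- any(emitted) && all(!vapply(all_cols[emitted], is.null, TRUE))
  colors <- if (col_ok) do.call(rbind, all_cols[emitted]) else NULL
  cloud <- point_cloud(pts, colors)
  attr(cloud, "provenance") <- do.call(rbind, all_prov)
  cloud
}
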