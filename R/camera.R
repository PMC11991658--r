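#' Calibrated pinhole camera view
#'
#' A `camera_view` bundles the calibration of one viewpoint: a world-to-camera
#' rigid transform, a pinhole intrinsic matrix, the image size, and the depth
#' sampling range used for plane-sweep hypotheses. The convention follows
#' MVSNet-style `cam.txt` files: the extrinsic maps world coordinates into the
#' camera frame (z forward), and pixel coordinates are 0-based with pixel
#' centers at integer coordinates, so the principal point `(cx, cy)` is the
#' sub-pixel position where the optical axis meets the image.
#'
#' @param intrinsic 3x3 pinhole matrix with `fx`, `fy` on the diagonal,
#'   principal point in the last column and zero skew.
#' @param extrinsic 4x4 rigid transform mapping world to camera coordinates;
#'   the upper-left 3x3 block must be a rotation (orthonormal, det +1).
#' @param width,height image size in pixels.
#' @param depth_min minimum depth hypothesis, millimetres (> 0).
#' @param depth_interval depth hypothesis spacing, millimetres (> 0).
#' @return An object of class `camera_view`.
#' @examples
#' v <- camera_view(intrinsic = matrix(c(100, 0, 0, 0, 100, 0, 50, 50, 1), 3),
#'                  extrinsic = diag(4), width = 100, height = 100,
#'                  depth_min = 400, depth_interval = 2.5)
#' project(v, matrix(c(0, 0, 500), 1))
#' @export
camera_view <- function(intrinsic, extrinsic, width, height,
                        depth_min, depth_interval) {
  intrinsic <- as_matrix33(intrinsic, "intrinsic")
  extrinsic <- as_matrix44(extrinsic, "extrinsic")
  R <- extrinsic[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
    stop("extrinsic rotation block must be orthonormal with det +1")
  fx <- intrinsic[1, 1]; fy <- intrinsic[2, 2]
  cx <- intrinsic[1, 3]; cy <- intrinsic[2, 3]
  if (!(fx > 0 && fy > 0)) stop("focal lengths must be positive")
  if (!(cx >= 0 && cx < width && cy >= 0 && cy < height))
    stop("principal point must lie inside the image")
  if (!(depth_min > 0)) stop("depth_min must be positive")
  if (!(depth_interval > 0)) stop("depth_interval must be positive")
  structure(
    list(intrinsic = intrinsic, extrinsic = extrinsic,
         width = as.integer(width), height = as.integer(height),
         depth_min = depth_min, depth_interval = depth_interval),
    class = "camera_view")
}

as_matrix33 <- function(m, what) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(3, 3)) || !all(is.finite(m)))
    stop(sprintf("%s must be a finite 3x3 matrix", what))
  storage.mode(m) <- "double"
  m
}

as_matrix44 <- function(m, what) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(4, 4)) || !all(is.finite(m)))
    stop(sprintf("%s must be a finite 4x4 matrix", what))
  storage.mode(m) <- "double"
  m
}

#' @export
print.camera_view <- function(x, ...) {
  cat(sprintf("<camera_view %dx%d px, fx=%.6g fy=%.6g, depth %.6g + k*%.6g mm>\n",
              x$width, x$height, x$intrinsic[1, 1], x$intrinsic[2, 2],
              x$depth_min, x$depth_interval))
  invisible(x)
}

#' Camera center in world coordinates
#'
#' @param view a [camera_view()].
#' @return Length-3 numeric vector, millimetres.
#' @export
camera_center <- function(view) {
  R <- view$extrinsic[1:3, 1:3]
  t <- view$extrinsic[1:3, 4]
  as.numeric(-crossprod(R, t))
}

as_points_matrix <- function(points, what = "points") {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  points <- as.matrix(points)
  if (ncol(points) != 3) stop(sprintf("%s must be an N x 3 matrix", what))
  storage.mode(points) <- "double"
  points
}

#' Project world points into a camera view
#'
#' Applies the world-to-camera transform and the pinhole intrinsics. Depths
#' are camera-frame z and may be non-positive for points behind the camera;
#' pixel coordinates for such points are unreliable and callers filter on the
#' returned `behind` flag.
#'
#' @param view a [camera_view()].
#' @param points_world N x 3 matrix of world points, millimetres.
#' @return A list with `pixels` (N x 2, 0-based x/y), `depths` (length N,
#'   camera-frame z in millimetres), and `behind` (logical, depth <= 0).
#' @export
project <- function(view, points_world) {
  points_world <- as_points_matrix(points_world)
  if (!all(is.finite(points_world))) stop("points must be finite (no NaN/Inf)")
  R <- view$extrinsic[1:3, 1:3]
  t <- view$extrinsic[1:3, 4]
  Xc <- points_world %*% t(R)
  Xc <- sweep(Xc, 2, -t) # add translation
  z <- Xc[, 3]
  fx <- view$intrinsic[1, 1]; fy <- view$intrinsic[2, 2]
  cx <- view$intrinsic[1, 3]; cy <- view$intrinsic[2, 3]
  s  <- view$intrinsic[1, 2] # skew, zero by invariant but honoured if present
  u <- (fx * Xc[, 1] + s * Xc[, 2]) / z + cx
  v <- fy * Xc[, 2] / z + cy
  list(pixels = cbind(x = u, y = v), depths = z, behind = z <= 0)
}

#' Back-project pixels to world points
#'
#' Inverse of [project()]: lifts 0-based pixel coordinates at given depths
#' (camera-frame z, millimetres) back to world coordinates.
#'
#' @param view a [camera_view()].
#' @param pixels N x 2 matrix (or length-2 vector) of 0-based pixel x/y.
#' @param depths length-N positive depths, millimetres.
#' @return N x 3 matrix of world points.
#' @export
backproject <- function(view, pixels, depths) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 2)
  pixels <- as.matrix(pixels)
  if (ncol(pixels) != 2) stop("pixels must be an N x 2 matrix")
  depths <- as.numeric(depths)
  if (length(depths) == 1 && nrow(pixels) > 1) depths <- rep(depths, nrow(pixels))
  if (length(depths) != nrow(pixels)) stop("one depth per pixel required")
  if (any(!is.finite(depths)) || any(depths <= 0))
    stop("depths must be finite and positive")
  Kinv <- solve(view$intrinsic)
  rays <- cbind(pixels[, 1], pixels[, 2], 1) %*% t(Kinv)
  Xc <- rays * depths
  R <- view$extrinsic[1:3, 1:3]
  t <- view$extrinsic[1:3, 4]
  sweep(Xc, 2, t) %*% R # (Xc - t) %*% R == t(R' %*% (Xc' - t))
}

#' Read an MVSNet-style cam.txt file
#'
#' Layout: a line `extrinsic`, four rows of four numbers, a blank line, a line
#' `intrinsic`, three rows of three numbers, a blank line, then one line with
#' `depth_min depth_interval` and optionally two further numbers which are
#' preserved as an attribute.
#'
#' @param path file path.
#' @param width,height image size in pixels (cam.txt does not store it).
#' @return A [camera_view()]; extra trailing depth numbers, if present, are
#'   kept in attribute `"depth_extra"`.
#' @export
read_cam_txt <- function(path, width, height) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  iext <- which(tolower(lines) == "extrinsic")[1]
  iint <- which(tolower(lines) == "intrinsic")[1]
  if (is.na(iext) || is.na(iint)) stop(sprintf("malformed cam file: %s", path))
  parse_rows <- function(rows) {
    do.call(rbind, lapply(rows, function(l) as.numeric(strsplit(l, "\\s+")[[1]])))
  }
  extr <- parse_rows(lines[(iext + 1):(iext + 4)])
  intr <- parse_rows(lines[(iint + 1):(iint + 3)])
  rest <- lines[(iint + 4):length(lines)]
  rest <- rest[nzchar(rest)]
  if (length(rest) < 1) stop(sprintf("missing depth line in cam file: %s", path))
  dnums <- as.numeric(strsplit(rest[1], "\\s+")[[1]])
  view <- camera_view(intr, extr, width, height,
                      depth_min = dnums[1], depth_interval = dnums[2])
  if (length(dnums) > 2) attr(view, "depth_extra") <- dnums[-(1:2)]
  view
}

#' Write an MVSNet-style cam.txt file
#'
#' @param view a [camera_view()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_cam_txt <- function(view, path) {
  fmt_row <- function(v) paste(sprintf("%.17g", v), collapse = " ")
  depth_line <- c(view$depth_min, view$depth_interval, attr(view, "depth_extra"))
  lines <- c("extrinsic",
             apply(view$extrinsic, 1, fmt_row),
             "",
             "intrinsic",
             apply(view$intrinsic, 1, fmt_row),
             "",
             fmt_row(depth_line))
  writeLines(lines, path)
  invisible(path)
}
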