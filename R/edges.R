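#' Binary edge mask
#'
#' @param values H x W logical matrix (TRUE = edge pixel).
#' @param source tag recording what the edges were computed from
#'   (`"rgb"` or `"depth"`).
#' @return An object of class `edge_mask`.
#' @export
edge_mask <- function(values, source = c("rgb", "depth")) {
  source <- match.arg(source)
  values <- as.matrix(values)
  if (!is.logical(values)) storage.mode(values) <- "logical"
  if (anyNA(values)) stop("edge mask must not contain NA")
  structure(list(values = values, source = source), class = "edge_mask")
}

#' @export
print.edge_mask <- function(x, ...) {
  cat(sprintf("<edge_mask %dx%d px, %d edge pixels, source=%s>\n",
              nrow(x$values), ncol(x$values), sum(x$values), x$source))
  invisible(x)
}

# ---- image helpers ---------------------------------------------------------

# Accepts H x W (gray) or H x W x 3 (RGB) arrays in [0,1] or [0,255];
# returns H x W luminance in [0,255].
to_luminance <- function(image) {
  image <- as_image_255(image)
  if (length(dim(image)) == 3) {
    0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  } else image
}

as_image_255 <- function(image) {
  if (is.null(dim(image))) stop("image must be a matrix or H x W x 3 array")
  if (length(image) == 0) stop("empty image")
  d <- dim(image)
  if (!(length(d) == 2 || (length(d) == 3 && d[3] %in% c(3, 4))))
    stop("image must be H x W or H x W x 3")
  if (length(d) == 3 && d[3] == 4) image <- image[, , 1:3, drop = FALSE] # drop alpha
  if (max(image) <= 1 + 1e-12) image <- image * 255
  image
}

# Separable Gaussian blur, reflective borders, kernel truncated at 3 sigma.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv_1d_rows <- function(m, k, r) {
    H <- nrow(m)
    # reflective index: reflect about the border pixel
    refl <- function(i) { i[i < 1] <- 2 - i[i < 1]; i[i > H] <- 2 * H - i[i > H]; i }
    out <- matrix(0, H, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * m[refl(seq_len(H) + j - r - 1L), , drop = FALSE]
    out
  }
  m <- conv_1d_rows(m, k, r)
  t(conv_1d_rows(t(m), k, r))
}

shift_mat <- function(m, dy, dx, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  ys <- max(1, 1 - dy):min(H, H - dy)
  xs <- max(1, 1 - dx):min(W, W - dx)
  out[ys, xs] <- m[ys + dy, xs + dx]
  out
}

# Sobel gradients; replicate borders so border gradients stay finite.
sobel_gradients <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- rbind(m[1, , drop = FALSE], m, m[H, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, W, drop = FALSE])
  s <- function(dy, dx) pad[(2 + dy):(H + 1 + dy), (2 + dx):(W + 1 + dx)]
  gx <- (s(-1, 1) + 2 * s(0, 1) + s(1, 1)) - (s(-1, -1) + 2 * s(0, -1) + s(1, -1))
  gy <- (s(1, -1) + 2 * s(1, 0) + s(1, 1)) - (s(-1, -1) + 2 * s(-1, 0) + s(-1, 1))
  list(gx = gx, gy = gy)
}

# ---- Canny -----------------------------------------------------------------

#' Canny edge detection
#'
#' Standard Canny pipeline: Gaussian smoothing, Sobel gradients, discrete
#' non-maximum suppression along the quantized gradient direction, and
#' double-threshold hysteresis (weak edges survive only when 8-connected to a
#' strong edge). RGB input is converted to luminance first. Thresholds apply
#' to the Sobel gradient magnitude of an 8-bit-range image; the defaults used
#' throughout the package for plant imagery are `low = 50`, `high = 150`.
#'
#' @param image H x W grayscale or H x W x 3 RGB array, `[0,1]` or `[0,255]`.
#' @param low,high hysteresis thresholds, `high > low > 0`.
#' @param sigma Gaussian pre-smoothing standard deviation in pixels.
#' @param magnitude `"l2"` (default) or `"l1"` norm of the Sobel responses.
#' @return An [edge_mask()] with source `"rgb"`.
#' @export
canny_edges <- function(image, low = 50, high = 150, sigma = 1.0,
                        magnitude = c("l2", "l1")) {
  magnitude <- match.arg(magnitude)
  if (!(high > low && low > 0)) stop("thresholds must satisfy high > low > 0")
  gray <- to_luminance(image)
  sm <- gaussian_blur(gray, sigma)
  g <- sobel_gradients(sm)
  mag <- if (magnitude == "l2") sqrt(g$gx^2 + g$gy^2) else abs(g$gx) + abs(g$gy)

  # non-maximum suppression: quantize direction into 4 sectors
  ang <- atan2(g$gy, g$gx)            # (-pi, pi]
  sector <- floor(((ang + pi) / (pi / 4)) %% 8 + 0.5) %% 4
  # neighbours along the gradient for each sector: 0 = horizontal (E/W),
  # 1 = diagonal NE/SW, 2 = vertical (N/S), 3 = diagonal NW/SE
  n1 <- matrix(0, nrow(mag), ncol(mag)); n2 <- n1
  for (s in 0:3) {
    d <- switch(as.character(s),
                "0" = c(0L, 1L), "1" = c(1L, 1L),
                "2" = c(1L, 0L), "3" = c(1L, -1L))
    sel <- sector == s
    n1[sel] <- shift_mat(mag, d[1], d[2])[sel]
    n2[sel] <- shift_mat(mag, -d[1], -d[2])[sel]
  }
  keep <- mag >= n1 & mag > n2
  strong <- keep & mag >= high
  weak <- keep & mag >= low
  edge_mask(cpp_hysteresis(weak, strong), source = "rgb")
}

#' Concatenate an edge channel onto an RGB image
#'
#' Builds the 4-channel (R, G, B, Edge) network input: the RGB bytes are
#' passed through untouched and the edge mask becomes a fourth channel with
#' values 255 (edge) and 0 (non-edge).
#'
#' @param rgb H x W x 3 array, `[0,1]` or `[0,255]`.
#' @param edges an [edge_mask()] of the same spatial size.
#' @return H x W x 4 integer-valued array of class `four_channel_image`,
#'   8-bit range, channels (R, G, B, Edge).
#' @export
concat_edge_channel <- function(rgb, edges) {
  stopifnot(inherits(edges, "edge_mask"))
  rgb <- as_image_255(rgb)
  if (length(dim(rgb)) != 3) stop("rgb must be an H x W x 3 array")
  if (!all(dim(rgb)[1:2] == dim(edges$values)))
    stop("rgb and edge mask sizes do not match")
  out <- array(0, dim = c(dim(rgb)[1:2], 4))
  out[, , 1:3] <- rgb
  out[, , 4] <- ifelse(edges$values, 255, 0)
  class(out) <- "four_channel_image"
  out
}

#' Edge mask of a ground-truth depth map
#'
#' Depth values are min-max normalized over the valid pixels to 8-bit range
#' (making the Canny thresholds scale-free across scenes), invalid pixels are
#' set to 0, Canny runs on the result, and the returned mask is restricted to
#' valid pixels.
#'
#' @param gt a [depth_map()] with at least one valid pixel.
#' @param low,high Canny hysteresis thresholds.
#' @param sigma Gaussian pre-smoothing in pixels.
#' @return An [edge_mask()] with source `"depth"`.
#' @export
depth_edge_mask <- function(gt, low = 50, high = 150, sigma = 1.0) {
  stopifnot(inherits(gt, "depth_map"))
  if (!any(gt$mask)) stop("depth map has no valid pixels")
  v <- gt$values
  rng <- range(v[gt$mask])
  img <- matrix(0, nrow(v), ncol(v))
  if (rng[2] > rng[1])
    img[gt$mask] <- (v[gt$mask] - rng[1]) / (rng[2] - rng[1]) * 255
  em <- canny_edges(img, low = low, high = high, sigma = sigma)
  edge_mask(em$values & gt$mask, source = "depth")
}

#' Read a PNG image as an 8-bit-range array
#'
#' @param path file path to a PNG.
#' @return H x W (gray) or H x W x 3 (RGB) array in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path))
  img <- png::readPNG(path)
  as_image_255(img)
}

#' Write an image array as PNG
#'
#' A 4-channel (R, G, B, Edge) image is stored in an RGBA container with the
#' edge channel in alpha.
#'
#' @param image H x W, H x W x 3 or H x W x 4 array, `[0,1]` or `[0,255]`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  img <- unclass(image)
  if (max(img) > 1 + 1e-12) img <- img / 255
  png::writePNG(img, path)
  invisible(path)
}
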