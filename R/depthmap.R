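#' Per-pixel metric depth map
#'
#' A `depth_map` stores per-pixel depth in millimetres as an H x W matrix in
#' which `0` encodes an invalid pixel (no depth). The validity mask is derived
#' from the values; an optional [camera_view()] ties the map to its viewpoint,
#' which fusion and reprojection require.
#'
#' @param values H x W numeric matrix, millimetres; 0 marks invalid pixels.
#'   All values must be finite and non-negative.
#' @param view optional [camera_view()] the map belongs to; when given, its
#'   image size must match `dim(values)`.
#' @return An object of class `depth_map` with fields `values`, `mask`, `view`.
#' @export
depth_map <- function(values, view = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) stop("depth values must be finite (no NaN/Inf)")
  if (any(values < 0)) stop("depth values must be non-negative")
  if (!is.null(view)) {
    stopifnot(inherits(view, "camera_view"))
    if (nrow(values) != view$height || ncol(values) != view$width)
      stop("depth map size does not match the camera view image size")
  }
  structure(list(values = values, mask = values > 0, view = view),
            class = "depth_map")
}

#' @export
print.depth_map <- function(x, ...) {
  cat(sprintf("<depth_map %dx%d px, %d valid, range [%.4g, %.4g] mm>\n",
              nrow(x$values), ncol(x$values), sum(x$mask),
              if (any(x$mask)) min(x$values[x$mask]) else NA,
              if (any(x$mask)) max(x$values[x$mask]) else NA))
  invisible(x)
}

#' Number of valid pixels of a depth map
#' @param depth a [depth_map()].
#' @return Integer count.
#' @export
n_valid <- function(depth) sum(depth$mask)

#' Read a PFM depth map
#'
#' Portable Float Map, single channel (`Pf`), scanlines stored bottom-up, byte
#' order given by the sign of the scale line (negative = little-endian, the
#' de-facto MVS interchange convention). Zeros decode to invalid pixels.
#'
#' @param path file path.
#' @param view optional [camera_view()] to attach.
#' @return A [depth_map()].
#' @export
read_pfm <- function(path, view = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    chars <- character(0)
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0) break
      if (grepl("^\\s$", ch)) { if (length(chars)) break else next }
      chars <- c(chars, ch)
    }
    paste(chars, collapse = "")
  }
  magic <- read_token()
  if (!magic %in% c("Pf", "PF")) stop(sprintf("not a PFM file: %s", path))
  if (magic == "PF") stop("3-channel PFM not supported for depth maps")
  w <- as.integer(read_token())
  h <- as.integer(read_token())
  scale <- as.numeric(read_token())
  endian <- if (scale < 0) "little" else "big"
  data <- readBin(con, "numeric", n = w * h, size = 4, endian = endian)
  if (length(data) != w * h) stop(sprintf("truncated PFM file: %s", path))
  if (abs(scale) != 1) data <- data * abs(scale)
  # scanlines bottom-up: first row read is the bottom image row
  m <- matrix(data, nrow = w, ncol = h)      # column = one scanline
  m <- t(m)[h:1, , drop = FALSE]             # flip to top-down rows
  depth_map(m, view = view)
}

#' Write a PFM depth map
#'
#' Little-endian, bottom-up scanlines, scale marker -1. Invalid pixels are
#' written as 0.
#'
#' @param depth a [depth_map()] (or plain matrix).
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(depth, path) {
  values <- if (inherits(depth, "depth_map")) depth$values else as.matrix(depth)
  h <- nrow(values); w <- ncol(values)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("Pf\n%d %d\n-1.000000\n", w, h), con, eos = NULL)
  bottom_up <- values[h:1, , drop = FALSE]
  writeBin(as.numeric(t(bottom_up)), con, size = 4, endian = "little")
  invisible(path)
}
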