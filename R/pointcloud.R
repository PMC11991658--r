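#' Unordered 3D point cloud
#'
#' Points are world-coordinate positions in millimetres; colors, when present,
#' are 0-255 RGB per point.
#'
#' @param points N x 3 numeric matrix, millimetres. `N = 0` is allowed.
#' @param colors optional N x 3 matrix in `[0, 255]`.
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points, colors = NULL) {
  if (is.null(points) || length(points) == 0) {
    points <- matrix(numeric(0), ncol = 3)
  }
  points <- as_points_matrix(points)
  if (!all(is.finite(points))) stop("point coordinates must be finite")
  colnames(points) <- c("x", "y", "z")
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    if (nrow(colors) != nrow(points) || ncol(colors) != 3)
      stop("colors must be an N x 3 matrix matching the points")
    if (any(colors < 0 | colors > 255)) stop("colors must lie in [0, 255]")
  }
  structure(list(points = points, colors = colors), class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud %d points%s>\n", nrow(x$points),
              if (is.null(x$colors)) "" else ", with color"))
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud a [point_cloud()].
#' @return Integer count.
#' @export
n_points <- function(cloud) nrow(cloud$points)

#' Read a PLY point cloud
#'
#' Supports ASCII and binary-little-endian PLY with a `vertex` element whose
#' leading properties include `x`, `y`, `z` (float or double) and optionally
#' `red`, `green`, `blue` (uchar). Non-vertex elements (e.g. faces) are
#' ignored when reading a cloud.
#'
#' @param path file path.
#' @return A [point_cloud()].
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_line <- function() {
    bytes <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1)
      if (length(b) == 0 || b == as.raw(10)) break
      bytes <- c(bytes, b)
    }
    sub("\r$", "", rawToChar(bytes))
  }
  if (read_line() != "ply") stop(sprintf("not a PLY file: %s", path))
  fmt <- NULL
  elements <- list() # list of list(name, count, props = data.frame(type, name))
  repeat {
    line <- read_line()
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0) next
    if (tok[1] == "comment") next
    if (tok[1] == "format") { fmt <- tok[2]; next }
    if (tok[1] == "element") {
      elements[[length(elements) + 1]] <-
        list(name = tok[2], count = as.integer(tok[3]), props = list())
      next
    }
    if (tok[1] == "property") {
      i <- length(elements)
      elements[[i]]$props[[length(elements[[i]]$props) + 1]] <-
        if (tok[2] == "list") list(type = "list", count_type = tok[3],
                                   item_type = tok[4], name = tok[5])
        else list(type = tok[2], name = tok[3])
      next
    }
    if (tok[1] == "end_header") break
  }
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop(sprintf("unsupported PLY format: %s", fmt))

  type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1,
                 short = 2, ushort = 2, int16 = 2, uint16 = 2,
                 int = 4, uint = 4, int32 = 4, uint32 = 4,
                 float = 4, float32 = 4, double = 8, float64 = 8)
  read_scalar <- function(type, n = 1) {
    if (type %in% c("float", "float32")) readBin(con, "numeric", n, size = 4, endian = "little")
    else if (type %in% c("double", "float64")) readBin(con, "numeric", n, size = 8, endian = "little")
    else if (type %in% c("uchar", "uint8", "char", "int8")) as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE, endian = "little"))
    else if (type %in% c("short", "int16")) as.numeric(readBin(con, "integer", n, size = 2, endian = "little"))
    else if (type %in% c("ushort", "uint16")) as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE, endian = "little"))
    else as.numeric(readBin(con, "integer", n, size = 4, endian = "little"))
  }

  points <- NULL; colors <- NULL
  for (el in elements) {
    pnames <- vapply(el$props, function(p) p$name, "")
    if (el$name == "vertex") {
      if (fmt == "ascii") {
        rows <- matrix(NA_real_, el$count, length(pnames))
        for (r in seq_len(el$count))
          rows[r, ] <- as.numeric(strsplit(trimws(read_line()), "\\s+")[[1]])
      } else {
        ptypes <- vapply(el$props, function(p) p$type, "")
        if (any(ptypes == "list"))
          stop("list properties on vertex element are not supported")
        if (all(ptypes %in% c("float", "float32"))) {
          # fast path: homogeneous float32 record
          flat <- readBin(con, "numeric", el$count * length(ptypes),
                          size = 4, endian = "little")
          rows <- matrix(flat, ncol = length(ptypes), byrow = TRUE)
        } else if (length(ptypes) == 6 &&
                   all(ptypes[1:3] %in% c("float", "float32")) &&
                   all(ptypes[4:6] %in% c("uchar", "uint8"))) {
          # fast path: xyz float32 + rgb uchar, 15-byte stride
          bytes <- readBin(con, "raw", el$count * 15L)
          base <- rep((seq_len(el$count) - 1L) * 15L, each = 12L)
          fidx <- base + rep(1:12, times = el$count)
          coords <- readBin(bytes[fidx], "numeric", el$count * 3L,
                            size = 4, endian = "little")
          cbase <- rep((seq_len(el$count) - 1L) * 15L, each = 3L)
          cidx <- cbase + rep(13:15, times = el$count)
          cols <- as.numeric(as.integer(bytes[cidx]))
          rows <- cbind(matrix(coords, ncol = 3, byrow = TRUE),
                        matrix(cols, ncol = 3, byrow = TRUE))
        } else {
          rows <- matrix(NA_real_, el$count, length(pnames))
          for (r in seq_len(el$count))
            for (ci in seq_along(el$props))
              rows[r, ci] <- read_scalar(el$props[[ci]]$type, 1)
        }
      }
      colnames(rows) <- pnames
      points <- rows[, c("x", "y", "z"), drop = FALSE]
      if (all(c("red", "green", "blue") %in% pnames))
        colors <- rows[, c("red", "green", "blue"), drop = FALSE]
    } else {
      # skip an unneeded element payload
      if (fmt == "ascii") {
        for (r in seq_len(el$count)) read_line()
      } else {
        for (r in seq_len(el$count)) {
          for (p in el$props) {
            if (p$type == "list") {
              cnt <- read_scalar(p$count_type, 1)
              read_scalar(p$item_type, cnt)
            } else read_scalar(p$type, 1)
          }
        }
      }
    }
  }
  if (is.null(points)) stop(sprintf("PLY file has no vertex element: %s", path))
  point_cloud(points, colors)
}

#' Write a PLY point cloud
#'
#' @param cloud a [point_cloud()].
#' @param path destination file.
#' @param binary write binary-little-endian (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path, binary = TRUE) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- n_points(cloud)
  has_color <- !is.null(cloud$colors)
  header <- c("ply",
              sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
              sprintf("element vertex %d", n),
              "property float x", "property float y", "property float z",
              if (has_color) c("property uchar red", "property uchar green",
                               "property uchar blue"),
              "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(header, collapse = "\n"), "\n"), con, eos = NULL)
  if (n == 0) return(invisible(path))
  if (binary) {
    if (has_color) {
      fb <- writeBin(as.numeric(t(cloud$points)), raw(), size = 4,
                     endian = "little")
      cb <- as.raw(as.integer(round(t(cloud$colors))))
      out <- raw(15L * n)
      base <- (seq_len(n) - 1L) * 15L
      out[rep(base, each = 12L) + rep(1:12, times = n)] <- fb
      out[rep(base, each = 3L) + rep(13:15, times = n)] <- cb
      writeBin(out, con)
    } else {
      writeBin(as.numeric(t(cloud$points)), con, size = 4, endian = "little")
    }
  } else {
    if (has_color) {
      lines <- sprintf("%.9g %.9g %.9g %d %d %d",
                       cloud$points[, 1], cloud$points[, 2], cloud$points[, 3],
                       as.integer(round(cloud$colors[, 1])),
                       as.integer(round(cloud$colors[, 2])),
                       as.integer(round(cloud$colors[, 3])))
    } else {
      lines <- sprintf("%.9g %.9g %.9g",
                       cloud$points[, 1], cloud$points[, 2], cloud$points[, 3])
    }
    writeChar(paste0(paste(lines, collapse = "\n"), "\n"), con, eos = NULL)
  }
  invisible(path)
}

#' Apply a rigid transform to points or a cloud
#'
#' @param x a [point_cloud()] or N x 3 matrix.
#' @param tf a [rigid_transform()].
#' @return Same type as `x`, transformed (`R x + t`).
#' @export
transform_points <- function(x, tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  if (inherits(x, "point_cloud")) {
    pts <- x$points %*% t(tf$rotation)
    pts <- sweep(pts, 2, -tf$translation)
    return(point_cloud(pts, x$colors))
  }
  pts <- as_points_matrix(x) %*% t(tf$rotation)
  sweep(pts, 2, -tf$translation)
}
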