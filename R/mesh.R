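#' Triangle mesh
#'
#' @param vertices V x 3 numeric matrix, millimetres.
#' @param faces F x 3 integer matrix of 1-based vertex indices; no face may
#'   repeat a vertex.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as_points_matrix(vertices, "vertices")
  faces <- as.matrix(faces)
  if (ncol(faces) != 3) stop("faces must be an F x 3 index matrix")
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0) {
    if (min(faces) < 1 || max(faces) > nrow(vertices))
      stop("face indices out of range")
    if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
            faces[, 1] == faces[, 3]))
      stop("degenerate faces (repeated vertex) are not allowed")
  }
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh %d vertices, %d faces, area %.6g mm^2>\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

#' Total surface area of a mesh
#'
#' Sum of triangle areas (half cross-product norms).
#'
#' @param mesh a [tri_mesh()].
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (nrow(mesh$faces) == 0) return(0)
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c_ <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  u <- b - a; v <- c_ - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Boundary edges of a mesh
#'
#' Edges incident to exactly one face — the open rim of a surface. A closed
#' surface has none.
#'
#' @param mesh a [tri_mesh()].
#' @return E x 2 integer matrix of vertex index pairs (possibly 0 rows).
#' @export
boundary_edges <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  f <- mesh$faces
  if (nrow(f) == 0) return(matrix(integer(0), ncol = 2))
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- paste(e[, 1], e[, 2])
  cnt <- table(key)
  single <- names(cnt)[cnt == 1]
  e[match(single, key), , drop = FALSE]
}

#' Median nearest-neighbour spacing of a cloud
#'
#' The median distance from each point to its nearest other point — the
#' characteristic sampling resolution used to scale mesh-filter radii.
#'
#' @param cloud a [point_cloud()] with >= 2 points.
#' @return Scalar spacing, millimetres.
#' @export
median_nn_spacing <- function(cloud) {
  pts <- if (inherits(cloud, "point_cloud")) cloud$points else as_points_matrix(cloud)
  if (nrow(pts) < 2) stop("spacing needs at least two points")
  median(cpp_nn_self(pts))
}

#' Reconstruct an open leaf surface from a point cloud
#'
#' Surface triangulation for leaf-like (open, locally height-field) point
#' clouds: the cloud is projected onto its principal (PCA) plane, Delaunay-
#' triangulated there, and triangles with any edge longer than
#' `filter_factor` times the cloud's characteristic spacing (the 95th
#' percentile nearest-neighbour distance, robust to both gridded and
#' Poisson-random sampling) are dropped.
#' The edge-length filter removes the over-extended triangles that span
#' concavities of the rim (the planar Delaunay covers the convex hull), after
#' which unreferenced vertices are discarded. This plays the role of surface
#' reconstruction plus vertex filtering in the leaf-edge segmentation
#' pipeline; it assumes an open surface that does not fold over its principal
#' plane (true of leaf patches, not of closed objects).
#'
#' @param cloud a [point_cloud()] with at least 100 points.
#' @param filter_factor triangle edge-length threshold as a multiple of the
#'   median point spacing (default 4).
#' @return A [tri_mesh()] whose vertices are (a subset of) the input points;
#'   the mapping back to input point indices is in attribute
#'   `"vertex_index"`.
#' @export
reconstruct_leaf_mesh <- function(cloud, filter_factor = 4) {
  stopifnot(inherits(cloud, "point_cloud"))
  pts <- cloud$points
  if (nrow(pts) < 100)
    stop("surface reconstruction needs at least 100 points")
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  pc <- svd(X, nu = 0, nv = 3)
  if (pc$d[2] < 1e-9 * max(pc$d))
    stop("degenerate cloud: points are (near-)collinear, no surface to reconstruct")
  uv <- X %*% pc$v[, 1:2]
  faces <- cpp_delaunay(uv[, 1], uv[, 2])
  # characteristic sampling scale; the 95th-percentile NN distance stays
  # meaningful for irregular (Poisson) sampling where the median is much
  # smaller than the mean inter-point distance
  spacing <- as.numeric(stats::quantile(cpp_nn_self(pts), 0.95))
  elen <- function(i, j) sqrt(rowSums((pts[faces[, i], , drop = FALSE] -
                                       pts[faces[, j], , drop = FALSE])^2))
  maxe <- pmax(elen(1, 2), elen(2, 3), elen(1, 3))
  faces <- faces[maxe <= filter_factor * spacing, , drop = FALSE]
  if (nrow(faces) == 0) stop("no triangles survive filtering; cloud too sparse or fragmented")
  used <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(pts))
  remap[used] <- seq_along(used)
  mesh <- tri_mesh(pts[used, , drop = FALSE],
                   matrix(remap[faces], ncol = 3))
  attr(mesh, "vertex_index") <- used
  attr(mesh, "spacing") <- spacing
  mesh
}

#' Segment the edge points of a leaf cloud
#'
#' Leaf-edge extraction pipeline: (1) mesh the leaf cloud with
#' [reconstruct_leaf_mesh()]; (2) find the mesh boundary (edges incident to
#' exactly one face); (3) return the input points lying within `d_th_mm` of
#' any boundary vertex (default 4 mm).
#'
#' @param leaf_cloud a [point_cloud()] of a single leaf (>= 100 points).
#' @param d_th_mm distance threshold to the boundary, millimetres.
#' @param filter_factor passed to [reconstruct_leaf_mesh()].
#' @return A list with `edge_cloud` (a [point_cloud()], subset of the input),
#'   `mesh` (the filtered [tri_mesh()]), `boundary` (boundary vertex
#'   positions) and `edge_index` (indices of edge points in the input cloud).
#' @export
segment_leaf_edges <- function(leaf_cloud, d_th_mm = 4, filter_factor = 4) {
  mesh <- reconstruct_leaf_mesh(leaf_cloud, filter_factor = filter_factor)
  be <- boundary_edges(mesh)
  if (nrow(be) == 0) {
    return(list(edge_cloud = point_cloud(NULL), mesh = mesh,
                boundary = matrix(numeric(0), ncol = 3),
                edge_index = integer(0)))
  }
  bverts <- mesh$vertices[sort(unique(as.vector(be))), , drop = FALSE]
  d <- cpp_nn(leaf_cloud$points, bverts)$dist
  idx <- which(d <= d_th_mm)
  list(edge_cloud = point_cloud(leaf_cloud$points[idx, , drop = FALSE],
                                if (!is.null(leaf_cloud$colors))
                                  leaf_cloud$colors[idx, , drop = FALSE] else NULL),
       mesh = mesh, boundary = bverts, edge_index = idx)
}

#' Write a mesh as ASCII PLY
#'
#' @param mesh a [tri_mesh()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_ply_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "tri_mesh"))
  header <- c("ply", "format ascii 1.0",
              sprintf("element vertex %d", nrow(mesh$vertices)),
              "property float x", "property float y", "property float z",
              sprintf("element face %d", nrow(mesh$faces)),
              "property list uchar int vertex_indices",
              "end_header")
  vlines <- sprintf("%.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2],
                    mesh$vertices[, 3])
  flines <- sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                    mesh$faces[, 3] - 1L)
  writeLines(c(header, vlines, flines), path)
  invisible(path)
}
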