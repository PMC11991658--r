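#' Plant height from a point cloud
#'
#' Height is the extent of the cloud along the up axis,
#' `H = max(z) - min(z)` — stem root to plant top. The up axis defaults to
#' world +z (the acquisition rig's vertical) and may be any axis name or unit
#' vector, e.g. for clouds registered in a different frame.
#'
#' @param cloud a non-empty [point_cloud()].
#' @param up_axis `"x"`, `"y"`, `"z"` or a length-3 vector (normalised
#'   internally).
#' @return Height in millimetres.
#' @export
plant_height <- function(cloud, up_axis = "z") {
  pts <- if (inherits(cloud, "point_cloud")) cloud$points else as_points_matrix(cloud)
  if (nrow(pts) == 0) stop("empty cloud has no height")
  if (is.character(up_axis)) {
    ax <- switch(match.arg(up_axis, c("x", "y", "z")),
                 x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  } else {
    ax <- as.numeric(up_axis)
    if (length(ax) != 3 || sum(ax^2) == 0) stop("up_axis must be a nonzero length-3 vector")
    ax <- ax / sqrt(sum(ax^2))
  }
  proj <- as.numeric(pts %*% ax)
  max(proj) - min(proj)
}

#' Leaf area from a leaf point cloud
#'
#' The leaf cloud is meshed with [reconstruct_leaf_mesh()] (surface
#' triangulation with over-extension filtering) and the area is the sum of
#' the triangle areas of the filtered mesh.
#'
#' @param leaf_cloud a [point_cloud()] of a single leaf (>= 100 points).
#' @param filter_factor passed to [reconstruct_leaf_mesh()].
#' @return Area in mm^2.
#' @export
leaf_area <- function(leaf_cloud, filter_factor = 4) {
  mesh_area(reconstruct_leaf_mesh(leaf_cloud, filter_factor = filter_factor))
}

#' Agreement statistics between measured and ground-truth traits
#'
#' Coefficient of determination
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - ybar)^2)` and mean absolute
#' percentage error `MAPE = (100/n) * sum(|y - yhat| / y)`, with `y` the
#' ground truth and `yhat` the measurement.
#'
#' @param truth numeric vector of ground-truth values (nonzero, non-constant).
#' @param measured numeric vector of the same length.
#' @return A list with `r2` and `mape` (percent).
#' @export
agreement_stats <- function(truth, measured) {
  truth <- as.numeric(truth); measured <- as.numeric(measured)
  if (length(truth) != length(measured)) stop("truth and measured lengths differ")
  if (length(truth) < 2) stop("need at least two paired samples")
  if (any(truth == 0)) stop("MAPE undefined: ground-truth value of zero")
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) stop("R^2 undefined: constant ground-truth vector")
  r2 <- 1 - sum((truth - measured)^2) / ss_tot
  mape <- 100 * mean(abs(truth - measured) / truth)
  list(r2 = r2, mape = mape)
}

#' Phenotype report for a plant reconstruction
#'
#' Plant height from the whole-plant cloud, per-leaf areas from segmented
#' leaf clouds, and — when ground truth is supplied — R^2 / MAPE agreement
#' statistics.
#'
#' @param cloud whole-plant [point_cloud()].
#' @param leaf_clouds optional list of per-leaf [point_cloud()]s.
#' @param truth optional data.frame with columns `true_area_mm2` (one row per
#'   leaf, matched by order) and/or `true_height_mm`.
#' @param up_axis passed to [plant_height()].
#' @return A list of class `phenotype_report` with `plant_height`,
#'   `leaf_area` (vector) and optional `area_agreement`.
#' @export
phenotype_report <- function(cloud, leaf_clouds = NULL, truth = NULL,
                             up_axis = "z") {
  areas <- if (length(leaf_clouds))
    vapply(leaf_clouds, leaf_area, numeric(1)) else numeric(0)
  rep <- list(plant_height = plant_height(cloud, up_axis), leaf_area = areas)
  if (!is.null(truth) && length(areas) >= 2 && "true_area_mm2" %in% names(truth))
    rep$area_agreement <- agreement_stats(truth$true_area_mm2[seq_along(areas)],
                                          areas)
  structure(rep, class = "phenotype_report")
}

#' @export
print.phenotype_report <- function(x, ...) {
  cat(sprintf("<phenotype_report: height %.4g mm; %d leaf area(s)%s>\n",
              x$plant_height, length(x$leaf_area),
              if (!is.null(x$area_agreement))
                sprintf("; area R2=%.4f MAPE=%.2f%%",
                        x$area_agreement$r2, x$area_agreement$mape) else ""))
  invisible(x)
}
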