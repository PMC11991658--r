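#' Nearest-neighbour distances between point clouds
#'
#' For every point of `from`, the Euclidean distance to its nearest neighbour
#' in `to`. Queries run through an exact kd-tree; results equal exhaustive
#' search.
#'
#' @param from,to non-empty [point_cloud()]s (or N x 3 matrices).
#' @return Numeric vector of length `n_points(from)`, millimetres.
#' @export
nn_distances <- function(from, to) {
  fp <- if (inherits(from, "point_cloud")) from$points else as_points_matrix(from)
  tp <- if (inherits(to, "point_cloud")) to$points else as_points_matrix(to)
  if (nrow(fp) == 0 || nrow(tp) == 0) stop("both clouds must be non-empty")
  cpp_nn(fp, tp)$dist
}

#' Accuracy / completeness evaluation of a reconstructed cloud
#'
#' Distance-based reconstruction metrics against a ground-truth cloud:
#' `MAE_Distance_1` is the mean reconstructed-to-truth nearest-neighbour
#' distance, `MAE_Distance_2` the mean truth-to-reconstructed distance, and
#' `MAE_Distance` their average. `Acc` is the percentage of reconstructed
#' points within `d_th` of the truth, `Comp` the percentage of truth points
#' within `d_th` of the reconstruction (strict `<`), and `OP` their mean.
#' The default threshold is 0.4 mm.
#'
#' @param rec reconstructed [point_cloud()].
#' @param gt ground-truth [point_cloud()].
#' @param d_th distance threshold, millimetres.
#' @return A list of class `cloud_eval_report` with fields `mae_distance_1`,
#'   `mae_distance_2`, `mae_distance` (mm), `acc`, `comp`, `op` (percent) and
#'   `d_th`.
#' @export
evaluate_clouds <- function(rec, gt, d_th = 0.4) {
  d1 <- nn_distances(rec, gt)
  d2 <- nn_distances(gt, rec)
  acc <- mean(d1 < d_th) * 100
  comp <- mean(d2 < d_th) * 100
  structure(list(
    mae_distance_1 = mean(d1),
    mae_distance_2 = mean(d2),
    mae_distance = (mean(d1) + mean(d2)) / 2,
    acc = acc, comp = comp, op = (acc + comp) / 2,
    d_th = d_th,
    n_rec = length(d1), n_gt = length(d2)
  ), class = "cloud_eval_report")
}

#' @export
print.cloud_eval_report <- function(x, ...) {
  cat(sprintf("<cloud_eval_report: MAE %.4g mm (rec->gt %.4g, gt->rec %.4g); Acc %.2f%% Comp %.2f%% OP %.2f%% @ %.3g mm>\n",
              x$mae_distance, x$mae_distance_1, x$mae_distance_2,
              x$acc, x$comp, x$op, x$d_th))
  invisible(x)
}

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 orthonormal matrix with det +1 (within 1e-6).
#' @param translation length-3 vector, millimetres.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as_matrix33(rotation, "rotation")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be orthonormal with det +1")
  translation <- as.numeric(translation)
  if (length(translation) != 3 || !all(is.finite(translation)))
    stop("translation must be a finite length-3 vector")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform: rotation %.4g deg, translation (%.4g, %.4g, %.4g) mm>\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

# Closed-form least-squares rigid fit (Kabsch / SVD of the cross-covariance)
# mapping rows of A onto rows of B.
kabsch <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(A, 2, ca), sweep(B, 2, cb))
  if (qr(H)$rank < 3)
    stop("degenerate geometry: cross-covariance rank < 3 (collinear or planar-degenerate points)")
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cb - as.numeric(R %*% ca)
  rigid_transform(R, t)
}

#' Point-to-point ICP registration
#'
#' Iterative closest point: alternates nearest-neighbour correspondence
#' (moving to fixed) with the closed-form SVD rigid update, until the RMS
#' correspondence distance improves by less than `tol` or `max_iter` is
#' reached. The RMS sequence is non-increasing. Coarse alignment is supplied
#' through `init`; this routine performs only the fine registration.
#'
#' @param moving,fixed [point_cloud()]s with at least 3 non-collinear points.
#' @param init initial [rigid_transform()] applied to `moving`.
#' @param max_iter iteration cap.
#' @param tol RMS improvement tolerance, millimetres.
#' @return A list with `transform` (the full moving-to-fixed
#'   [rigid_transform()], incorporating `init`), `rms` (final RMS, mm),
#'   `rms_trace` (per-iteration RMS) and `iterations`.
#' @export
icp_point_to_point <- function(moving, fixed, init = rigid_transform(),
                               max_iter = 50, tol = 1e-6) {
  stopifnot(inherits(moving, "point_cloud"), inherits(fixed, "point_cloud"),
            inherits(init, "rigid_transform"))
  if (n_points(moving) < 3 || n_points(fixed) < 3)
    stop("ICP requires at least 3 points in each cloud")
  M0 <- moving$points
  R <- init$rotation; t <- init$translation
  rms_trace <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    M <- sweep(M0 %*% t(R), 2, -t)
    nn <- cpp_nn(M, fixed$points)
    rms <- sqrt(mean(nn$dist^2))
    rms_trace <- c(rms_trace, rms)
    if (prev - rms < tol && it > 1) break
    prev <- rms
    corr <- fixed$points[nn$index, , drop = FALSE]
    upd <- kabsch(M0, corr)
    R <- upd$rotation; t <- upd$translation
  }
  list(transform = rigid_transform(R, t), rms = rms_trace[length(rms_trace)],
       rms_trace = rms_trace, iterations = length(rms_trace))
}
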