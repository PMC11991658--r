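#' Discretized depth-hypothesis grid
#'
#' Plane-sweep MVS networks classify each pixel over K discrete depth
#' hypotheses `d_k = d_min + k * delta` for `k = 0 .. K-1`, with
#' `delta = (d_max - d_min) / (K - 1)` so the grid spans `[d_min, d_max]`
#' inclusively. The training configuration this package mirrors spans
#' 425-935 mm with 48, 32 and 8 hypotheses over the three refinement stages.
#'
#' @param d_min,d_max grid end points, millimetres, `d_max > d_min`.
#' @param K number of hypotheses (>= 1).
#' @return An object of class `depth_grid` with field `values` (length K,
#'   strictly increasing).
#' @export
depth_grid <- function(d_min, d_max, K) {
  K <- as.integer(K)
  if (K < 1) stop("K must be >= 1")
  if (K > 1 && !(d_max > d_min)) stop("d_max must exceed d_min")
  values <- if (K == 1) d_min else d_min + (d_max - d_min) / (K - 1) * (0:(K - 1))
  structure(list(d_min = d_min, d_max = d_max, K = K, values = values),
            class = "depth_grid")
}

#' Index of the hypothesis nearest to a true depth
#'
#' Returns the 0-based index `argmin_k |d_k - d_true|`, with ties broken
#' toward the smaller index; depths outside the grid clamp to the nearest end.
#'
#' @param grid a [depth_grid()].
#' @param d_true numeric vector of depths, millimetres (finite).
#' @return Integer vector of 0-based hypothesis indices.
#' @export
nearest_hypothesis <- function(grid, d_true) {
  stopifnot(inherits(grid, "depth_grid"))
  d_true <- as.numeric(d_true)
  if (any(!is.finite(d_true))) stop("d_true must be finite")
  if (grid$K == 1) return(rep(0L, length(d_true)))
  delta <- (grid$d_max - grid$d_min) / (grid$K - 1)
  k <- (d_true - grid$d_min) / delta
  lower <- pmin(pmax(floor(k), 0), grid$K - 1)
  upper <- pmin(lower + 1, grid$K - 1)
  d_lo <- grid$values[lower + 1]
  d_up <- grid$values[upper + 1]
  idx <- ifelse(abs(d_true - d_lo) <= abs(d_true - d_up), lower, upper)
  as.integer(idx)
}

#' Per-pixel probability volume over depth hypotheses
#'
#' @param probs H x W x K array, per-pixel distribution over the hypotheses
#'   of `grid`; non-negative, and summing to 1 (within 1e-5) at every pixel.
#' @param grid a [depth_grid()] with matching K.
#' @return An object of class `probability_volume`.
#' @export
probability_volume <- function(probs, grid) {
  stopifnot(inherits(grid, "depth_grid"))
  probs <- as.array(probs)
  d <- dim(probs)
  if (length(d) != 3 || d[3] != grid$K)
    stop("probs must be H x W x K with K matching the grid")
  if (any(probs < 0)) stop("probabilities must be non-negative")
  sums <- apply(probs, c(1, 2), sum)
  if (max(abs(sums - 1)) > 1e-5)
    stop("per-pixel probabilities must sum to 1 (within 1e-5)")
  structure(list(probs = probs, grid = grid), class = "probability_volume")
}

#' Focal loss over a depth probability volume
#'
#' Pixel-wise classification loss over depth hypotheses,
#' `L = (1/N) * sum_i -(1 - P_i)^gamma * log(P_i)`, where `P_i` is the
#' predicted probability at the hypothesis nearest to the ground-truth depth
#' of valid pixel `i` and N counts the valid pixels. `gamma` down-weights
#' well-classified pixels (`gamma = 0` reduces to mean cross-entropy); the
#' natural logarithm is used and probabilities are floored at 1e-12.
#'
#' @param vol a [probability_volume()] spatially aligned with `gt`.
#' @param gt a [depth_map()] with at least one valid pixel.
#' @param gamma focusing parameter (>= 0); default 2.
#' @return Scalar loss (non-negative).
#' @export
focal_loss <- function(vol, gt, gamma = 2) {
  stopifnot(inherits(vol, "probability_volume"), inherits(gt, "depth_map"))
  if (gamma < 0) stop("gamma must be >= 0")
  d <- dim(vol$probs)
  if (!all(d[1:2] == dim(gt$values)))
    stop("probability volume and depth map are not spatially aligned")
  valid <- which(gt$mask)
  if (length(valid) == 0) stop("no valid pixels in the ground-truth depth map")
  k <- nearest_hypothesis(vol$grid, gt$values[valid])
  # linear index into H x W x K array
  hw <- d[1] * d[2]
  p <- vol$probs[valid + hw * k]
  p <- pmax(p, 1e-12)
  mean(-(1 - p)^gamma * log(p))
}

#' Gradient-magnitude map of a depth image
#'
#' Central differences in the interior, one-sided differences at borders,
#' magnitude `sqrt(gx^2 + gy^2)`. A difference involving an invalid neighbor
#' falls back to the one-sided difference on the valid side, and to zero when
#' no valid neighbor exists, so invalid regions do not leak spurious
#' gradients.
#'
#' @param depth a [depth_map()] (or plain matrix, all pixels valid).
#' @param operator `"central"` (default) or `"sobel"`.
#' @return H x W numeric matrix of gradient magnitudes (mm per pixel).
#' @export
depth_gradient_magnitude <- function(depth, operator = c("central", "sobel")) {
  operator <- match.arg(operator)
  if (inherits(depth, "depth_map")) {
    v <- depth$values; mask <- depth$mask
  } else {
    v <- as.matrix(depth); mask <- matrix(TRUE, nrow(v), ncol(v))
  }
  if (operator == "sobel") {
    g <- sobel_gradients(v)
    return(sqrt((g$gx / 8)^2 + (g$gy / 8)^2)) # /8: unit response to unit slope
  }
  H <- nrow(v); W <- ncol(v)
  vm <- v; vm[!mask] <- 0
  directional <- function(dy, dx) {
    fwd_v <- shift_mat(vm, dy, dx); fwd_m <- shift_mat(mask, dy, dx, fill = FALSE)
    bwd_v <- shift_mat(vm, -dy, -dx); bwd_m <- shift_mat(mask, -dy, -dx, fill = FALSE)
    g <- matrix(0, H, W)
    both <- fwd_m & bwd_m
    g[both] <- (fwd_v[both] - bwd_v[both]) / 2
    fo <- fwd_m & !bwd_m
    g[fo] <- fwd_v[fo] - vm[fo]
    bo <- bwd_m & !fwd_m
    g[bo] <- vm[bo] - bwd_v[bo]
    g
  }
  gx <- directional(0, 1)
  gy <- directional(1, 0)
  sqrt(gx^2 + gy^2)
}

#' Edge-aware loss between ground-truth and predicted depth
#'
#' Mean absolute difference of depth-gradient magnitudes restricted to the
#' edge-mask pixels: `L = (1/M) * sum_j E_j * |G_gt,j - G_pred,j|`, where `E`
#' is the (binary) edge mask of the ground-truth depth image, `G` the
#' gradient-magnitude map, and M the number of masked pixels valid in both
#' maps. An empty mask yields 0 (no edge supervision available) with a
#' message.
#'
#' @param gt,pred [depth_map()]s of equal size.
#' @param mask an [edge_mask()] (typically from [depth_edge_mask()]).
#' @param operator gradient operator, see [depth_gradient_magnitude()].
#' @return Scalar loss (non-negative).
#' @export
edge_aware_loss <- function(gt, pred, mask, operator = c("central", "sobel")) {
  stopifnot(inherits(gt, "depth_map"), inherits(pred, "depth_map"),
            inherits(mask, "edge_mask"))
  if (!all(dim(gt$values) == dim(pred$values)) ||
      !all(dim(gt$values) == dim(mask$values)))
    stop("gt, pred and mask must be spatially aligned")
  sel <- mask$values & gt$mask & pred$mask
  if (!any(sel)) {
    message("edge-aware loss: empty edge mask, returning 0")
    return(0)
  }
  g_gt <- depth_gradient_magnitude(gt, operator = operator)
  g_pr <- depth_gradient_magnitude(pred, operator = operator)
  mean(abs(g_gt[sel] - g_pr[sel]))
}

#' Loss configuration
#'
#' @param gamma focal-loss focusing parameter (default 2).
#' @param stage_weights 3 x 2 matrix of per-stage weights
#'   `(lambda1, lambda2)` for the focal and edge-aware terms; default
#'   `0.9 / 0.1` for each of the three coarse-to-fine stages.
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(gamma = 2,
                        stage_weights = matrix(c(0.9, 0.1), 3, 2, byrow = TRUE)) {
  stage_weights <- as.matrix(stage_weights)
  if (ncol(stage_weights) != 2) stop("stage_weights must have two columns")
  if (gamma < 0 || any(stage_weights < 0))
    stop("gamma and all stage weights must be >= 0")
  structure(list(gamma = gamma, stage_weights = stage_weights),
            class = "loss_config")
}

#' Staged total training loss
#'
#' Weighted sum of the focal and edge-aware losses over the coarse-to-fine
#' stages: `L = sum_s lambda1_s * L_focal_s + lambda2_s * L_edge_s`.
#'
#' @param stages list of 1-3 stages, each a list with elements `vol`
#'   ([probability_volume()]), `pred` and `gt` ([depth_map()]s) and `mask`
#'   (an [edge_mask()]).
#' @param config a [loss_config()].
#' @return A list with `total` (scalar) and `stages` (data.frame breakdown
#'   with the per-stage focal and edge terms and weights).
#' @export
total_loss <- function(stages, config = loss_config()) {
  stopifnot(inherits(config, "loss_config"))
  ns <- length(stages)
  if (ns < 1) stop("at least one stage is required")
  if (ns > nrow(config$stage_weights))
    stop("more stages than stage weights configured")
  rows <- lapply(seq_len(ns), function(s) {
    st <- stages[[s]]
    lf <- focal_loss(st$vol, st$gt, gamma = config$gamma)
    le <- edge_aware_loss(st$gt, st$pred, st$mask)
    data.frame(stage = s,
               lambda1 = config$stage_weights[s, 1],
               lambda2 = config$stage_weights[s, 2],
               focal = lf, edge = le,
               weighted = config$stage_weights[s, 1] * lf +
                 config$stage_weights[s, 2] * le)
  })
  breakdown <- do.call(rbind, rows)
  list(total = sum(breakdown$weighted), stages = breakdown)
}
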