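eval_set <- function(gt, pred, region_mask = NULL) {
  stopifnot(inherits(gt, "depth_map"), inherits(pred, "depth_map"))
  if (!all(dim(gt$values) == dim(pred$values)))
    stop("gt and pred depth maps must have the same size")
  sel <- gt$mask & pred$mask
  if (!is.null(region_mask)) {
    region_mask <- if (inherits(region_mask, "edge_mask")) region_mask$values
                   else as.matrix(region_mask)
    if (!all(dim(region_mask) == dim(gt$values)))
      stop("region mask size does not match the depth maps")
    sel <- sel & region_mask
  }
  sel
}

#' Mean absolute depth error
#'
#' `MAE = (1/Nz) * sum_i |D_gt,i - D_pred,i|` over the evaluation set: pixels
#' valid in both maps (prediction holes are excluded, not scored) and inside
#' the optional region mask.
#'
#' @param gt,pred [depth_map()]s of equal size.
#' @param region_mask optional H x W logical matrix (or [edge_mask()])
#'   restricting the evaluation region.
#' @return Scalar MAE in millimetres.
#' @export
mae_depth <- function(gt, pred, region_mask = NULL) {
  sel <- eval_set(gt, pred, region_mask)
  if (!any(sel)) stop("empty evaluation set")
  mean(abs(gt$values[sel] - pred$values[sel]))
}

#' Fraction of pixels with depth error below a threshold (EPE_n)
#'
#' The proportion of evaluation pixels whose absolute depth error is strictly
#' below `threshold_mm` (so `EPE_2` and `EPE_4` are the 2 mm and 4 mm rates).
#'
#' @param gt,pred [depth_map()]s of equal size.
#' @param threshold_mm error threshold, millimetres.
#' @param region_mask optional region restriction, see [mae_depth()].
#' @return Fraction in `[0, 1]`.
#' @export
epe_fraction <- function(gt, pred, threshold_mm, region_mask = NULL) {
  sel <- eval_set(gt, pred, region_mask)
  if (!any(sel)) stop("empty evaluation set")
  mean(abs(gt$values[sel] - pred$values[sel]) < threshold_mm)
}

#' Annular edge region of a plant mask
#'
#' The band of mask pixels within `width_px` (Euclidean pixel distance) of
#' the mask complement — the ring extending inward from the silhouette edge
#' in which leaf-edge depth errors are assessed (40 px in the protocol this
#' package implements). Everything outside the image counts as complement,
#' so a mask touching the border contributes a band there too.
#'
#' @param plant_mask H x W logical matrix.
#' @param width_px band width, pixels (>= 1).
#' @return H x W logical matrix; always a subset of `plant_mask`.
#' @export
edge_annulus_mask <- function(plant_mask, width_px = 40) {
  plant_mask <- as.matrix(plant_mask)
  if (!is.logical(plant_mask)) storage.mode(plant_mask) <- "logical"
  if (!(width_px >= 1)) stop("width_px must be >= 1")
  if (!any(plant_mask)) return(plant_mask)
  H <- nrow(plant_mask); W <- ncol(plant_mask)
  padded <- matrix(FALSE, H + 2, W + 2)
  padded[2:(H + 1), 2:(W + 1)] <- plant_mask
  d <- cpp_edt(padded)[2:(H + 1), 2:(W + 1), drop = FALSE]
  plant_mask & d <= width_px
}

#' Mean and sample standard deviation across samples
#'
#' Cross-sample summary used to report per-plant metric variability:
#' arithmetic mean and the n-1 (sample) standard deviation.
#'
#' @param per_sample_values numeric vector, length >= 2.
#' @return Named numeric vector `c(mean, sd)`.
#' @export
summarize_samples <- function(per_sample_values) {
  x <- as.numeric(per_sample_values)
  if (length(x) < 2) stop("at least two samples are required for a standard deviation")
  c(mean = mean(x), sd = sd(x))
}

#' Full depth-map evaluation report
#'
#' Computes the overall MAE, the edge-annulus MAE, and EPE fractions at the
#' requested thresholds, over the both-valid (optionally plant-masked)
#' evaluation set.
#'
#' @param gt,pred [depth_map()]s of equal size.
#' @param plant_mask optional H x W logical plant mask; defaults to the
#'   ground-truth validity mask.
#' @param edge_width_px edge annulus width, pixels (default 40).
#' @param epe_thresholds numeric vector of EPE thresholds in millimetres.
#' @return A list of class `depth_eval_report`: `mae_overall`, `mae_edge`,
#'   `epe` (named vector), `n_valid`, `n_edge`, `n_excluded` (gt-valid pixels
#'   dropped because the prediction had no depth there).
#' @export
evaluate_depth <- function(gt, pred, plant_mask = NULL, edge_width_px = 40,
                           epe_thresholds = c(2, 4)) {
  if (is.null(plant_mask)) plant_mask <- gt$mask
  sel <- eval_set(gt, pred, plant_mask)
  if (!any(sel)) stop("empty evaluation set")
  annulus <- edge_annulus_mask(plant_mask, edge_width_px)
  edge_sel <- sel & annulus
  epe <- vapply(epe_thresholds, function(th) epe_fraction(gt, pred, th, plant_mask),
                numeric(1))
  names(epe) <- sprintf("epe_%g", epe_thresholds)
  structure(list(
    mae_overall = mean(abs(gt$values[sel] - pred$values[sel])),
    mae_edge = if (any(edge_sel)) mean(abs(gt$values[edge_sel] - pred$values[edge_sel]))
               else NA_real_,
    epe = epe,
    n_valid = sum(sel),
    n_edge = sum(edge_sel),
    n_excluded = sum(gt$mask & plant_mask & !pred$mask)
  ), class = "depth_eval_report")
}

#' @export
print.depth_eval_report <- function(x, ...) {
  cat(sprintf("<depth_eval_report: MAE %.4g mm (edge %.4g mm), %s, n=%d (edge %d, excluded %d)>\n",
              x$mae_overall, x$mae_edge,
              paste(sprintf("%s=%.3f", names(x$epe), x$epe), collapse = " "),
              x$n_valid, x$n_edge, x$n_excluded))
  invisible(x)
}
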