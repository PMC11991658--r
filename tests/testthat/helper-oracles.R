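# Unvectorized brute-force oracles, written independently of the package
# internals; each loops over pixels/points explicitly.

oracle_mae_depth <- function(gt_values, pred_values) {
  tot <- 0; n <- 0
  for (i in seq_len(nrow(gt_values))) {
    for (j in seq_len(ncol(gt_values))) {
      if (gt_values[i, j] > 0 && pred_values[i, j] > 0) {
        tot <- tot + abs(gt_values[i, j] - pred_values[i, j])
        n <- n + 1
      }
    }
  }
  tot / n
}

oracle_epe <- function(gt_values, pred_values, threshold) {
  hits <- 0; n <- 0
  for (i in seq_len(nrow(gt_values))) {
    for (j in seq_len(ncol(gt_values))) {
      if (gt_values[i, j] > 0 && pred_values[i, j] > 0) {
        n <- n + 1
        if (abs(gt_values[i, j] - pred_values[i, j]) < threshold) hits <- hits + 1
      }
    }
  }
  hits / n
}

oracle_nn_dist <- function(from, to) {
  out <- numeric(nrow(from))
  for (i in seq_len(nrow(from))) {
    best <- Inf
    for (j in seq_len(nrow(to))) {
      d <- sqrt(sum((from[i, ] - to[j, ])^2))
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

oracle_focal <- function(probs, gt_values, grid_values, gamma) {
  tot <- 0; n <- 0
  for (i in seq_len(nrow(gt_values))) {
    for (j in seq_len(ncol(gt_values))) {
      if (gt_values[i, j] > 0) {
        best_k <- 1; best_d <- Inf
        for (k in seq_along(grid_values)) {
          d <- abs(grid_values[k] - gt_values[i, j])
          if (d < best_d) { best_d <- d; best_k <- k }
        }
        p <- max(probs[i, j, best_k], 1e-12)
        tot <- tot + -(1 - p)^gamma * log(p)
        n <- n + 1
      }
    }
  }
  tot / n
}

# gradient magnitude by explicit loops: central differences in the interior,
# one-sided at borders / next to invalid pixels, zero with no valid neighbour
oracle_grad_mag <- function(values, mask) {
  H <- nrow(values); W <- ncol(values)
  g <- matrix(0, H, W)
  at <- function(i, j) if (i >= 1 && i <= H && j >= 1 && j <= W && mask[i, j])
    values[i, j] else NA
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      gx <- 0; gy <- 0
      r <- at(i, j + 1); l <- at(i, j - 1)
      if (!is.na(r) && !is.na(l)) gx <- (r - l) / 2
      else if (!is.na(r) && mask[i, j]) gx <- r - values[i, j]
      else if (!is.na(l) && mask[i, j]) gx <- values[i, j] - l
      d <- at(i + 1, j); u <- at(i - 1, j)
      if (!is.na(d) && !is.na(u)) gy <- (d - u) / 2
      else if (!is.na(d) && mask[i, j]) gy <- d - values[i, j]
      else if (!is.na(u) && mask[i, j]) gy <- values[i, j] - u
      g[i, j] <- sqrt(gx^2 + gy^2)
    }
  }
  g
}

oracle_edge_loss <- function(gt_values, pred_values, edge_mask) {
  gm <- gt_values > 0
  pm <- pred_values > 0
  g_gt <- oracle_grad_mag(gt_values, gm)
  g_pr <- oracle_grad_mag(pred_values, pm)
  tot <- 0; n <- 0
  for (i in seq_len(nrow(gt_values))) {
    for (j in seq_len(ncol(gt_values))) {
      if (edge_mask[i, j] && gm[i, j] && pm[i, j]) {
        tot <- tot + abs(g_gt[i, j] - g_pr[i, j])
        n <- n + 1
      }
    }
  }
  if (n == 0) 0 else tot / n
}

oracle_r2_mape <- function(truth, measured) {
  n <- length(truth)
  ybar <- sum(truth) / n
  ss_res <- 0; ss_tot <- 0; ape <- 0
  for (i in seq_len(n)) {
    ss_res <- ss_res + (truth[i] - measured[i])^2
    ss_tot <- ss_tot + (truth[i] - ybar)^2
    ape <- ape + abs(truth[i] - measured[i]) / truth[i]
  }
  list(r2 = 1 - ss_res / ss_tot, mape = 100 * ape / n)
}

oracle_mean_sd <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  c(mean = m, sd = sqrt(ss / (n - 1)))
}

# Euclidean distance of every TRUE pixel to the nearest FALSE pixel, with
# everything outside the image counted as FALSE (matches the annulus
# convention). Quadratic scan.
oracle_dist_to_complement <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  bg <- which(!mask, arr.ind = TRUE)
  out <- matrix(Inf, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      if (!mask[i, j]) { out[i, j] <- 0; next }
      best <- min(i, j, H - i + 1, W - j + 1)^2 # nearest out-of-image pixel
      if (nrow(bg) > 0) {
        d2 <- (bg[, 1] - i)^2 + (bg[, 2] - j)^2
        best <- min(best, min(d2))
      }
      out[i, j] <- sqrt(best)
    }
  }
  out
}

random_depth_pair <- function(H = 16, W = 16, seed = 42, invalid_frac = 0.2) {
  set.seed(seed)
  gt <- matrix(runif(H * W, 400, 600), H, W)
  pred <- gt + matrix(rnorm(H * W, 0, 3), H, W)
  gt[matrix(runif(H * W) < invalid_frac, H, W)] <- 0
  pred[matrix(runif(H * W) < invalid_frac, H, W)] <- 0
  pred <- pmax(pred, 0)
  list(gt = gt, pred = pred)
}
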