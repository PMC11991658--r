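test_that("nearest_hypothesis matches exhaustive argmin with declared ties", {
  g <- depth_grid(425, 935, 48)
  expect_equal(nearest_hypothesis(g, 425), 0L)
  expect_equal(nearest_hypothesis(g, 935), 47L)
  # exact midpoint between d_0 and d_1 resolves to the smaller index
  mid <- (g$values[1] + g$values[2]) / 2
  expect_equal(nearest_hypothesis(g, mid), 0L)
  # clamping outside the range
  expect_equal(nearest_hypothesis(g, 100), 0L)
  expect_equal(nearest_hypothesis(g, 2000), 47L)
  set.seed(4)
  d <- runif(10000, 300, 1100)
  brute <- vapply(d, function(x) {
    k <- which.min(abs(g$values - x)) # which.min takes the first (smaller) tie
    as.integer(k - 1)
  }, integer(1))
  expect_identical(nearest_hypothesis(g, d), brute)
})

test_that("focal loss is zero at certainty and matches the closed form for uniform volumes", {
  g <- depth_grid(400, 470, 8)
  gt <- depth_map(matrix(g$values[3], 4, 4))
  probs <- array(0, c(4, 4, 8)); probs[, , 3] <- 1
  expect_equal(focal_loss(probability_volume(probs, g), gt, gamma = 2), 0)
  uni <- array(1 / 8, c(4, 4, 8))
  expect_equal(focal_loss(probability_volume(uni, g), gt, gamma = 2),
               (1 - 1 / 8)^2 * log(8), tolerance = 1e-12)
  expect_error(focal_loss(probability_volume(uni, g), depth_map(matrix(0, 4, 4))),
               "valid")
})

test_that("focal loss at gamma 0 reduces to cross-entropy and matches the loop oracle", {
  set.seed(7)
  H <- 16; W <- 16; K <- 6
  g <- depth_grid(400, 500, K)
  raw <- array(runif(H * W * K), c(H, W, K))
  probs <- sweep(raw, c(1, 2), apply(raw, c(1, 2), sum), "/")
  gtv <- matrix(runif(H * W, 390, 510), H, W)
  gtv[sample(H * W, 30)] <- 0
  gt <- depth_map(gtv)
  vol <- probability_volume(probs, g)
  for (gamma in c(0, 2)) {
    expect_equal(focal_loss(vol, gt, gamma),
                 oracle_focal(probs, gtv, g$values, gamma), tolerance = 1e-10)
  }
  # strictly decreasing in the probability at the true hypothesis
  p2 <- probs
  i <- which(gtv > 0)[1]
  k_true <- nearest_hypothesis(g, gtv[i]) + 1
  bump <- 0.2 * p2[, , k_true][i]
  arr <- p2[, , k_true]; arr[i] <- arr[i] + bump; p2[, , k_true] <- arr
  p2 <- sweep(p2, c(1, 2), apply(p2, c(1, 2), sum), "/")
  expect_lt(focal_loss(probability_volume(p2, g), gt, 2), focal_loss(vol, gt, 2))
})

test_that("edge-aware loss vanishes for equal or offset predictions", {
  set.seed(8)
  vals <- matrix(runif(25, 450, 550), 5, 5)
  gt <- depth_map(vals)
  mask <- edge_mask(matrix(TRUE, 5, 5))
  expect_equal(edge_aware_loss(gt, gt, mask), 0)
  expect_equal(edge_aware_loss(gt, depth_map(vals + 30), mask), 0, tolerance = 1e-12)
})

test_that("edge-aware loss on the 5x5 ramp equals the hand-computed 10.0", {
  x <- matrix(rep(0:4, each = 5), 5, 5) # column index, 0-based
  gt <- depth_map(10 * x + 10)          # +10 keeps column 0 valid
  pred <- depth_map(20 * x + 10)
  mask <- matrix(FALSE, 5, 5); mask[2:4, 3] <- TRUE # interior column
  expect_equal(edge_aware_loss(gt, pred, edge_mask(mask)), 10.0)
})

test_that("edge-aware loss with an empty mask returns zero with a message", {
  gt <- depth_map(matrix(500, 4, 4))
  expect_message(val <- edge_aware_loss(gt, gt, edge_mask(matrix(FALSE, 4, 4))),
                 "empty")
  expect_equal(val, 0)
})

test_that("edge-aware loss matches the unvectorized oracle on random fixtures", {
  for (seed in 1:3) {
    pair <- random_depth_pair(16, 16, seed = seed)
    set.seed(seed + 100)
    mask <- matrix(runif(256) < 0.3, 16, 16)
    got <- suppressMessages(
      edge_aware_loss(depth_map(pair$gt), depth_map(pair$pred), edge_mask(mask)))
    expect_equal(got, oracle_edge_loss(pair$gt, pair$pred, mask),
                 tolerance = 1e-10)
  }
})

test_that("total loss combines stages with the 0.9/0.1 weights", {
  # a stage engineered to have focal 2.0 and edge 4.0:
  # focal: uniform probability p with -(1-p)^2 log p = 2 is awkward; instead
  # build exact values from simple fixtures and check the weighting rule via
  # a stub computed from the real parts
  g <- depth_grid(400, 470, 8)
  gtv <- matrix(g$values[4], 6, 6)
  gt <- depth_map(gtv)
  uni <- array(1 / 8, c(6, 6, 8))
  vol <- probability_volume(uni, g)
  x <- matrix(rep(0:5, each = 6), 6, 6)
  pred <- depth_map(gtv + 5 * x)
  mask <- edge_mask(matrix(TRUE, 6, 6))
  st <- list(vol = vol, gt = gt, pred = pred, mask = mask)
  lf <- focal_loss(vol, gt, 2)
  le <- edge_aware_loss(gt, pred, mask)
  one <- total_loss(list(st), loss_config())
  expect_equal(one$total, 0.9 * lf + 0.1 * le, tolerance = 1e-12)
  three <- total_loss(list(st, st, st), loss_config())
  expect_equal(three$total, 3 * one$total, tolerance = 1e-12)
  # linear in the stage weights
  cfg2 <- loss_config(stage_weights = matrix(c(1.8, 0.2), 3, 2, byrow = TRUE))
  expect_equal(total_loss(list(st), cfg2)$total, 2 * one$total, tolerance = 1e-12)
  expect_error(total_loss(list(), loss_config()), "at least one")
})

test_that("the worked 2.2 example: focal 2.0, edge 4.0, weights (0.9, 0.1)", {
  # check the weighting arithmetic the way it is specified, on known terms
  expect_equal(0.9 * 2.0 + 0.1 * 4.0, 2.2)
  # and that total_loss reproduces exactly this combination for stages whose
  # component losses are measured first
  g <- depth_grid(100, 800, 8)
  gtv <- matrix(g$values[5], 8, 8)
  vol <- probability_volume(array(1 / 8, c(8, 8, 8)), g)
  x <- matrix(rep(0:7, each = 8), 8, 8)
  st <- list(vol = vol, gt = depth_map(gtv), pred = depth_map(gtv + 3 * x),
             mask = edge_mask(matrix(TRUE, 8, 8)))
  res <- total_loss(list(st))
  expect_equal(res$total,
               0.9 * res$stages$focal[1] + 0.1 * res$stages$edge[1],
               tolerance = 1e-12)
})

test_that("probability volumes reject malformed distributions", {
  g <- depth_grid(400, 470, 4)
  bad <- array(1, c(2, 2, 4))
  expect_error(probability_volume(bad, g), "sum to 1")
  neg <- array(c(-0.1, 1.1, rep(0.5, 14)), c(2, 2, 4))
  expect_error(probability_volume(neg, g), "non-negative")
  expect_error(probability_volume(array(0.25, c(2, 2, 3)), g), "K")
  expect_error(depth_grid(500, 400, 8), "exceed")
})
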