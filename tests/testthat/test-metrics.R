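# Brute-force oracles: every ratio metric recomputed from explicit pixel
# enumeration, independent of the package's vectorized implementations.

dice_oracle <- function(s, g) {
  inter <- 0; ns <- 0; ng <- 0
  for (i in seq_along(s)) {
    if (s[i] && g[i]) inter <- inter + 1
    if (s[i]) ns <- ns + 1
    if (g[i]) ng <- ng + 1
  }
  if (ns + ng == 0) 1 else 2 * inter / (ns + ng)
}

bf_oracle <- function(pred, truth, tol) {
  bnd <- function(m) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
      if (!m[r, c]) next
      interior <- TRUE
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || cc < 1 || rr > nrow(m) || cc > ncol(m) || !m[rr, cc])
          interior <- FALSE
      }
      out[r, c] <- !interior
    }
    out
  }
  pb <- which(bnd(pred != 0), arr.ind = TRUE)
  tb <- which(bnd(truth != 0), arr.ind = TRUE)
  if (!nrow(pb) && !nrow(tb)) return(1)
  if (!nrow(pb) || !nrow(tb)) return(0)
  mind <- function(a, b) vapply(seq_len(nrow(a)), function(i)
    sqrt(min((a[i, 1] - b[, 1])^2 + (a[i, 2] - b[, 2])^2)), 1)
  p <- mean(mind(pb, tb) <= tol)
  r <- mean(mind(tb, pb) <= tol)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

test_that("confusion counts equal a hand tally and sum to the pixel count", {
  p <- matrix(c(0, 1, 1, 2, 0, 1, 2, 2, 0, 0, 1, 1, 2, 0, 1, 0), 4, 4)
  g <- matrix(c(0, 1, 2, 2, 0, 0, 2, 1, 0, 0, 1, 2, 2, 0, 1, 1), 4, 4)
  cts <- confusion(p, g, 3)
  expect_equal(unclass(cts), confusion_oracle(p, g, 3), ignore_attr = TRUE)
  expect_true(all(rowSums(cts) == 16))
  # perfect agreement
  all1 <- matrix(1L, 10, 10)
  c2 <- confusion(all1, all1, 3)
  expect_equal(c2[2, "TP"], 100L)
  expect_equal(c2[2, "FP"] + c2[2, "FN"], 0L)
  # total disagreement: truth all 0, pred all 1
  c3 <- confusion(matrix(1L, 10, 10), matrix(0L, 10, 10), 3)
  expect_equal(c3[2, "FP"], 100L)
  expect_error(confusion(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("dice handles the textbook cases and equals its oracle", {
  a <- matrix(FALSE, 10, 10); a[1:5, 1:10] <- TRUE   # half plane
  expect_equal(dice(a, a), 1)
  b <- !a
  expect_equal(dice(a, b), 0)
  # |S|=|G|=100, overlap 50
  s <- matrix(FALSE, 10, 20); s[, 1:10] <- TRUE
  g <- matrix(FALSE, 10, 20); g[, 6:15] <- TRUE
  expect_equal(dice(s, g), 0.5)
  expect_equal(dice(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4)), 1)
})

test_that("dice statistics use the population standard deviation", {
  expect_equal(dice_statistics(c(0.8, 0.8, 0.8)), c(mean = 0.8, sd = 0))
  expect_equal(dice_statistics(c(0, 1)), c(mean = 0.5, sd = 0.5))
  # the six reported validation-set scores, against the independent oracle
  v <- c(0.8281, 0.8279, 0.8235, 0.8233, 0.8261, 0.8249)
  mu <- sum(v) / length(v)
  sd_pop <- sqrt(sum((v - mu)^2) / length(v))
  got <- dice_statistics(v)
  expect_equal(unname(got["mean"]), mu)
  expect_equal(unname(got["mean"]), 0.82563, tolerance = 1e-5)
  expect_equal(unname(got["sd"]), sd_pop)
  expect_error(dice_statistics(numeric(0)), "at least one")
})

test_that("iou follows TP/(TP+FP+FN) with the both-empty convention", {
  p <- matrix(0L, 10, 10); p[1:5, ] <- 1L
  cts <- confusion(p, p, 3)
  expect_equal(iou(cts, 0), 1)
  expect_equal(iou(cts, 1), 1)
  expect_equal(iou(cts, 2), 1)   # absent class scores 1
  expect_equal(mean_iou(cts), 1)
  fake <- structure(matrix(c(50, 25, 25, 0), 1, 4,
                           dimnames = list(NULL, c("TP", "FP", "FN", "TN"))),
                    class = "confusion_counts")
  expect_equal(iou(fake, 0), 0.5)
})

test_that("precision and recall use the standard ratios", {
  fake <- structure(matrix(c(80, 20, 0, 0), 1, 4,
                           dimnames = list(NULL, c("TP", "FP", "FN", "TN"))),
                    class = "confusion_counts")
  expect_equal(precision_recall(fake, 0), c(precision = 0.8, recall = 1))
  # a recall of a fully missed class is 0, not the absent-class convention
  missed <- structure(matrix(c(0, 0, 10, 90), 1, 4,
                             dimnames = list(NULL, c("TP", "FP", "FN", "TN"))),
                      class = "confusion_counts")
  expect_equal(unname(precision_recall(missed, 0)["recall"]), 0)
  p <- matrix(1L, 5, 5)
  expect_equal(precision_recall(confusion(p, p, 2), 1),
               c(precision = 1, recall = 1))
})

test_that("recall can never exceed 1", {
  set.seed(12)
  for (i in 1:50) {
    mp <- random_mask_pair(8, 8)
    cts <- confusion(mp$pred, mp$truth, 3)
    for (cl in 0:2) {
      pr <- precision_recall(cts, cl)
      expect_lte(pr["recall"], 1)
      expect_lte(pr["precision"], 1)
    }
  }
})

test_that("boundary F1 matches a pairwise-distance oracle", {
  # identical masks
  m <- matrix(FALSE, 16, 16); m[4:10, 4:10] <- TRUE
  expect_equal(boundary_f1(m, m), 1)
  # one-pixel shift within tolerance 2
  m2 <- matrix(FALSE, 16, 16); m2[5:11, 4:10] <- TRUE
  expect_equal(boundary_f1(m, m2, 2), 1)
  # far-apart small squares
  a <- matrix(FALSE, 16, 16); a[2:3, 2:3] <- TRUE
  b <- matrix(FALSE, 16, 16); b[12:13, 12:13] <- TRUE
  expect_equal(boundary_f1(a, b, 2), 0)
  # empty cases
  e <- matrix(FALSE, 16, 16)
  expect_equal(boundary_f1(e, e), 1)
  expect_equal(boundary_f1(m, e), 0)
  set.seed(23)
  for (i in 1:30) {
    mp <- random_mask_pair(12, 12, 2)
    expect_equal(boundary_f1(mp$pred == 1, mp$truth == 1, 2),
                 bf_oracle(mp$pred == 1, mp$truth == 1, 2), tolerance = 1e-12)
  }
})

test_that("rmse covers exact, constant and inverted predictions", {
  g <- matrix(sample(0:1, 64, TRUE), 8, 8)
  expect_equal(rmse(g + 0, g), 0)
  expect_equal(rmse(matrix(0.5, 8, 8), g), 0.5)
  expect_equal(rmse(1 - g, g), 1)
  expect_equal(rmse(matrix(0.6, 8, 8), g, hard = TRUE),
               sqrt(mean((1 - g)^2)))
  expect_error(rmse(matrix(1.5, 8, 8), g), "0, 1")
})

test_that("all ratio metrics agree with brute-force enumeration on random masks", {
  set.seed(77)
  for (i in 1:200) {
    mp <- random_mask_pair(16, 16)
    cts <- confusion(mp$pred, mp$truth, 3)
    expect_equal(unclass(cts), confusion_oracle(mp$pred, mp$truth, 3),
                 ignore_attr = TRUE)
    for (cl in 0:2) {
      s <- mp$pred == cl; g <- mp$truth == cl
      expect_equal(dice(s, g), dice_oracle(s, g), tolerance = 1e-12)
      tp <- sum(s & g); fp <- sum(s & !g); fn <- sum(!s & g)
      io_ref <- if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)
      expect_equal(iou(cts, cl), io_ref, tolerance = 1e-12)
      pr <- precision_recall(cts, cl)
      if (tp + fp > 0)
        expect_equal(unname(pr["precision"]), tp / (tp + fp), tolerance = 1e-12)
      if (tp + fn > 0)
        expect_equal(unname(pr["recall"]), tp / (tp + fn), tolerance = 1e-12)
    }
    expect_equal(pixel_accuracy(mp$pred, mp$truth), mean(mp$pred == mp$truth))
  }
})

test_that("Dice and IoU satisfy their algebraic identity on random masks", {
  set.seed(99)
  for (i in 1:100) {
    mp <- random_mask_pair(16, 16, 2)
    cts <- confusion(mp$pred, mp$truth, 2)
    for (cl in 0:1) {
      d <- dice(mp$pred == cl, mp$truth == cl)
      io <- iou(cts, cl)
      expect_equal(d, 2 * io / (1 + io), tolerance = 1e-12)
    }
  }
})

test_that("dice and boundary F1 are symmetric and Dice grows with overlap", {
  set.seed(13)
  for (i in 1:20) {
    mp <- random_mask_pair(12, 12, 2)
    s <- mp$pred == 1; g <- mp$truth == 1
    expect_equal(dice(s, g), dice(g, s))
    expect_equal(boundary_f1(s, g), boundary_f1(g, s))
  }
  # nested masks: growing overlap never decreases Dice or IoU
  g <- matrix(FALSE, 16, 16); g[4:13, 4:13] <- TRUE
  prev_d <- -1; prev_i <- -1
  for (k in 4:13) {
    s <- matrix(FALSE, 16, 16); s[4:k, 4:13] <- TRUE
    s[14:16, 1:3] <- TRUE  # fixed off-target area keeps |S| comparable
    d <- dice(s, g)
    cts <- confusion(ifelse(s, 1L, 0L), ifelse(g, 1L, 0L), 2)
    io <- iou(cts, 1)
    expect_gte(d, prev_d); expect_gte(io, prev_i)
    prev_d <- d; prev_i <- io
  }
})

test_that("metrics_report aggregates every quantity coherently", {
  sc <- generate_scene(scene_spec(seed = 61))
  truth <- sc$labels$labels
  rep1 <- metrics_report(truth, truth,
                         probs = {
                           pr <- array(0, c(64, 64, 3))
                           for (cl in 0:2) pr[, , cl + 1] <- (truth == cl) + 0
                           pr
                         })
  expect_equal(rep1$accuracy, 1)
  expect_equal(rep1$dice_mean, 1)
  expect_equal(rep1$mean_iou, 1)
  expect_equal(rep1$mean_bf, 1)
  expect_equal(max(rep1$rmse_per_class), 0)
  # all-background prediction scores 0 Dice on present vegetation
  rep0 <- metrics_report(matrix(0L, 64, 64), truth)
  expect_equal(rep0$dice_per_class[2], 0)
  expect_equal(rep0$dice_per_class[3], 0)
})
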