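test_that("matching handles the canonical hand cases", {
  # identical tables
  s <- spot_table(data.frame(y = runif(5, 0, 50), x = runif(5, 0, 50)))
  m <- match_spots(s, s)
  expect_equal(m$tp, 5)
  expect_equal(m$fp, 0)
  expect_equal(m$fn, 0)
  expect_true(all(m$pairs$distance == 0))
  # a uniform 4 px offset is outside the 3 px cutoff
  off <- s; off$x <- off$x + 4
  m4 <- match_spots(off, s)
  expect_equal(c(m4$tp, m4$fp, m4$fn), c(0, 5, 5))
  # but inside a 5 px cutoff
  expect_equal(match_spots(off, s, match_config(cutoff = 5))$tp, 5)
  # one near, one far prediction
  gt <- spot_table(data.frame(y = 0, x = 0))
  pred <- spot_table(data.frame(y = c(1, 10), x = c(0, 10)))
  m2 <- match_spots(pred, gt)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(1, 1, 0))
  expect_equal(m2$pairs$distance, 1)
})

test_that("metric formulas match hand computation and conventions", {
  gt <- spot_table(data.frame(y = 0, x = 0))
  pred <- spot_table(data.frame(y = c(1, 10), x = c(0, 10)))
  met <- compute_metrics(match_spots(pred, gt))
  expect_equal(met$precision, 0.5)
  expect_equal(met$recall, 1)
  expect_equal(met$f1, 2 / 3)
  expect_equal(met$distance_error, 1)
  # perfect match
  p <- compute_metrics(match_spots(gt, gt))
  expect_equal(p$f1, 1)
  expect_equal(p$distance_error, 0)
  # empty vs empty: perfect by convention
  e <- compute_metrics(match_spots(spot_table(), spot_table()))
  expect_equal(e$f1, 1)
  expect_equal(e$distance_error, 0)
  # no matches with points present: f1 = 0, distance undefined
  far <- spot_table(data.frame(y = c(50, 60, 70), x = c(50, 60, 70)))
  two <- spot_table(data.frame(y = c(0, 5), x = c(0, 5)))
  u <- compute_metrics(match_spots(far, two))
  expect_equal(u$f1, 0)
  expect_true(is.na(u$distance_error))
})

test_that("the grid-pruned greedy matcher equals brute-force enumeration", {
  set.seed(41)
  for (trial in 1:200) {
    nd <- sample(2:3, 1)
    np <- sample(0:12, 1)
    ng <- sample(0:12, 1)
    axes <- if (nd == 2) c("y", "x") else c("z", "y", "x")
    mk <- function(n) {
      spot_table(as.data.frame(setNames(
        lapply(seq_len(nd), function(i) runif(n, 0, 15)), axes)))
    }
    pred <- mk(np); gt <- mk(ng)
    cutoff <- runif(1, 1, 5)
    ours <- match_spots(pred, gt, match_config(cutoff))
    ref <- brute_match(pred, gt, cutoff)
    expect_equal(ours$tp, ref$tp)
    if (ours$tp) {
      expect_equal(ours$pairs$gt, ref$pairs$gt)
      expect_equal(ours$pairs$pred, ref$pairs$pred)
      expect_equal(ours$pairs$distance, ref$pairs$distance)
    }
    expect_true(all(ours$pairs$distance < cutoff))
    expect_equal(ours$fp, np - ours$tp)
    expect_equal(ours$fn, ng - ours$tp)
  }
})

test_that("tp is symmetric and F1 is monotone in the cutoff", {
  set.seed(42)
  pred <- spot_table(data.frame(y = runif(15, 0, 30), x = runif(15, 0, 30)))
  gt <- spot_table(data.frame(y = runif(12, 0, 30), x = runif(12, 0, 30)))
  for (cutoff in c(1, 2, 4)) {
    a <- match_spots(pred, gt, match_config(cutoff))
    b <- match_spots(gt, pred, match_config(cutoff))
    expect_equal(a$tp, b$tp)
    expect_equal(a$fp, b$fn)
  }
  f1s <- vapply(c(0.5, 1, 2, 3, 5), function(cf) {
    compute_metrics(match_spots(pred, gt, match_config(cf)))$f1
  }, 0)
  expect_true(all(diff(f1s) >= 0))
})

test_that("dataset evaluation reports medians with the NA convention", {
  t1 <- spot_table(data.frame(y = c(1, 2), x = c(1, 2)))
  t2 <- spot_table(data.frame(y = 1, x = 1))
  t2off <- spot_table(data.frame(y = 2, x = 1))   # distance 1, still TP
  far <- spot_table(data.frame(y = 50, x = 50))
  rep <- evaluate_dataset(list(t1, t2off, far), list(t1, t2, t2))
  expect_equal(rep$per_image$f1, c(1, 1, 0))
  expect_equal(rep$median_f1, 1)
  # the unmatched image contributes no distance error
  expect_equal(rep$median_distance_error, 0.5)
  expect_error(evaluate_dataset(list(t1), list(t1, t2)), "lengths")
})

test_that("jittered predictions reproduce the chi-distribution distance error", {
  set.seed(55)
  sigma <- 0.5
  des <- vapply(1:50, function(i) {
    gt <- spot_table(data.frame(y = runif(40, 5, 120), x = runif(40, 5, 120)))
    pred <- gt
    pred$y <- pred$y + rnorm(40, 0, sigma)
    pred$x <- pred$x + rnorm(40, 0, sigma)
    compute_metrics(match_spots(pred, gt))$distance_error
  }, 0)
  # mean of a chi(2) variable scaled by sigma: sigma * sqrt(pi / 2)
  expected <- sigma * sqrt(pi / 2)
  se <- sd(des) / sqrt(length(des))
  expect_lt(abs(mean(des) - expected), 3 * se + 0.01)
})
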