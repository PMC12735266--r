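test_that("identical point sets match perfectly", {
  pts <- data.frame(row = c(1, 10, 20), col = c(2, 11, 5))
  m <- match_points(pts, pts, 6)
  expect_equal(nrow(m$pairs), 3)
  expect_equal(m$pairs$distance, rep(0, 3))
  s <- detection_scores(m)
  expect_equal(c(s$precision, s$recall, s$f1), c(1, 1, 1))
  expect_equal(mean_localization_error(m), 0)
})

test_that("nearest prediction wins and extras become false positives", {
  gt <- data.frame(row = 0, col = 0)
  pred <- data.frame(row = c(0, 0), col = c(5, 7))
  m <- match_points(gt, pred, 6)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$distance, 5)
  expect_equal(m$pairs$pred, 1)
  s <- detection_scores(m)
  expect_equal(s$precision, 0.5)
  expect_equal(s$recall, 1)
  expect_equal(s$f1, 2 / 3)
})

test_that("counts always partition both point sets", {
  set.seed(21)
  for (i in 1:25) {
    ng <- sample(0:6, 1); np <- sample(0:6, 1)
    gt <- data.frame(row = runif(ng, 0, 30), col = runif(ng, 0, 30))
    pred <- data.frame(row = runif(np, 0, 30), col = runif(np, 0, 30))
    s <- detection_scores(match_points(gt, pred, 6))
    expect_equal(s$tp + s$fn, ng)
    expect_equal(s$tp + s$fp, np)
  }
})

test_that("empty-set conventions hold", {
  none <- data.frame(row = numeric(0), col = numeric(0))
  some <- data.frame(row = 1, col = 1)
  s1 <- detection_scores(match_points(none, none, 6))
  expect_equal(c(s1$precision, s1$recall), c(1, 1))
  s2 <- detection_scores(match_points(some, none, 6))
  expect_equal(c(s2$recall, s2$f1), c(0, 0))
  s3 <- detection_scores(match_points(none, some, 6))
  expect_equal(c(s3$precision, s3$f1), c(0, 0))
  expect_error(mean_localization_error(match_points(none, none, 6)),
               "undefined")
})

test_that("localization error averages matches and penalizes the rest", {
  gt <- data.frame(row = c(0, 0, 50), col = c(0, 10, 50))
  pred <- data.frame(row = c(2, 0), col = c(0, 14))
  m <- match_points(gt, pred, 6)   # distances 2 and 4; one gt unmatched
  expect_equal(sort(m$pairs$distance), c(2, 4))
  expect_equal(mean_localization_error(m, penalty = 16), (2 + 4 + 16) / 3)
  expect_equal(mean_localization_error(m), (2 + 4 + m$threshold) / 3)
})

test_that("scores ignore the ordering of the point lists", {
  set.seed(22)
  gt <- data.frame(row = runif(8, 0, 40), col = runif(8, 0, 40))
  pred <- data.frame(row = runif(9, 0, 40), col = runif(9, 0, 40))
  s1 <- detection_scores(match_points(gt, pred, 8))
  perm_g <- sample(8); perm_p <- sample(9)
  s2 <- detection_scores(match_points(gt[perm_g, ], pred[perm_p, ], 8))
  expect_equal(s1[c("precision", "recall", "f1")],
               s2[c("precision", "recall", "f1")])
})

test_that("greedy matching is bounded by and almost always equals the optimum", {
  # Greedy nearest-first can in principle lose a match to "blocking"
  # (its first pick consuming the only prediction a second target could
  # use: gt1 near both preds, gt2 near only one, the shared pred
  # nearest to gt1).  Such configurations are rare for uniform points
  # at this density; what must always hold is TP_greedy <= TP_optimal.
  set.seed(23)
  n_diff <- 0L
  for (i in 1:1000) {
    ng <- sample(0:3, 1); np <- sample(0:3, 1)
    gt <- data.frame(row = runif(ng, 0, 40), col = runif(ng, 0, 40))
    pred <- data.frame(row = runif(np, 0, 40), col = runif(np, 0, 40))
    sg <- detection_scores(match_points(gt, pred, 6))
    so <- detection_scores(match_points(gt, pred, 6, method = "optimal"))
    expect_lte(sg$tp, so$tp)
    if (sg$tp != so$tp) n_diff <- n_diff + 1L
  }
  expect_lte(n_diff, 2L)
})

test_that("crossing 2x2 configurations resolve like the brute-force assignment", {
  gt <- data.frame(row = c(0, 4), col = c(0, 0))
  pred <- data.frame(row = c(3, 1), col = c(0, 0))
  m <- match_points(gt, pred, 6)
  # brute force over both complete assignments
  d <- as.matrix(dist(rbind(gt, pred)))[1:2, 3:4]
  best <- min(d[1, 1] + d[2, 2], d[1, 2] + d[2, 1])
  expect_equal(sum(m$pairs$distance), best)
  expect_equal(nrow(m$pairs), 2)
})

test_that("one-call evaluation returns the full metric set", {
  gt <- data.frame(row = c(5, 10), col = c(5, 10))
  pred <- data.frame(row = c(5, 30), col = c(6, 30))
  s <- evaluate_detections(gt, pred, 6)
  expect_equal(s$tp, 1); expect_equal(s$fp, 1); expect_equal(s$fn, 1)
  expect_equal(s$mle, (1 + 6 + 6) / 3)
})
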