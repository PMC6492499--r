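test_that("matching is inclusive at the tolerance and one-to-one", {
  expect_equal(nrow(match_detections(matrix(c(0, 0, 0), 1),
                                     matrix(c(1.2, 0, 0), 1), 1.2)), 1L)
  expect_equal(nrow(match_detections(matrix(c(0, 0, 0), 1),
                                     matrix(c(1.3, 0, 0), 1), 1.2)), 0L)
  gt <- rbind(c(0, 0, 0), c(1, 0, 0))
  det <- matrix(c(0.5, 0, 0), 1)
  expect_equal(nrow(match_detections(gt, det, 1.2)), 1L)
})

test_that("greedy matching equals the optimal matching on small instances", {
  set.seed(21)
  for (trial in 1:25) {
    gt <- matrix(runif(3 * sample(1:8, 1), 0, 5), ncol = 3)
    det <- matrix(runif(3 * sample(1:8, 1), 0, 5), ncol = 3)
    pairs <- match_detections(gt, det, 1.2)
    expect_equal(nrow(pairs), max_matching_oracle(gt, det, 1.2))
    expect_true(all(pairs$distance <= 1.2 + 1e-9))
    expect_equal(anyDuplicated(pairs$gt_id), 0L)
    expect_equal(anyDuplicated(pairs$det_id), 0L)
  }
})

test_that("metrics follow the P/N, P/M and harmonic-mean definitions", {
  pts <- matrix(runif(30), ncol = 3)
  r <- compute_metrics(pts, pts, 1.2)
  expect_equal(c(r$precision, r$recall, r$f1), c(1, 1, 1))
  gt <- cbind(seq(0, 45, by = 5), 0, 0)     # 10 points far apart
  det <- cbind(seq(0, 35, by = 5) + 0.3, 0, 0)  # 8 points, all matched
  r <- compute_metrics(gt, det, 1.2)
  expect_equal(c(r$M, r$N, r$P), c(10, 8, 8))
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 0.8)
  expect_equal(r$f1, 8 / 9)
})

test_that("empty detection sets give zero metrics with a warning", {
  gt <- matrix(runif(9), ncol = 3)
  expect_warning(r <- compute_metrics(gt, gt[0, , drop = FALSE], 1.2),
                 "no detections")
  expect_equal(c(r$precision, r$recall, r$f1), c(0, 0, 0))
})

test_that("swapping ground truth and detections swaps precision and recall", {
  set.seed(22)
  a <- matrix(runif(24, 0, 4), ncol = 3)
  b <- matrix(runif(15, 0, 4), ncol = 3)
  r1 <- compute_metrics(a, b, 1.2)
  r2 <- compute_metrics(b, a, 1.2)
  expect_equal(r1$precision, r2$recall)
  expect_equal(r1$recall, r2$precision)
  expect_equal(r1$P, r2$P)
})

test_that("matching is invariant to row order of either input", {
  set.seed(23)
  gt <- matrix(runif(30, 0, 3), ncol = 3)
  det <- matrix(runif(30, 0, 3), ncol = 3)
  p1 <- match_detections(gt, det, 1.2)
  perm <- sample(nrow(det))
  p2 <- match_detections(gt, det[perm, ], 1.2)
  expect_equal(nrow(p1), nrow(p2))
  expect_equal(sort(p1$distance), sort(p2$distance))
})
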