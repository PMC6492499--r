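test_that("average filtering preserves constants and matches hand values", {
  I <- array(7, c(9, 9, 9))
  expect_equal(estimate_background(I, c(3, 3, 3), passes = 2), I)
  J <- array(0, c(9, 9, 9)); J[5, 5, 5] <- 1
  C1 <- estimate_background(J, c(3, 3, 3), passes = 1)
  expect_equal(C1[5, 5, 5], 1 / 27)
  expect_equal(C1[4, 5, 5], 1 / 27)
  expect_equal(C1[3, 5, 5], 0)
  # two passes equal one pass applied twice
  expect_equal(estimate_background(J, c(3, 3, 3), passes = 2),
               estimate_background(C1, c(3, 3, 3), passes = 1))
  expect_error(estimate_background(J, c(11, 3, 3)), "larger")
  expect_error(estimate_background(J, c(4, 3, 3)), "odd")
})

test_that("masked background estimation ignores unsupported voxels", {
  I <- array(0, c(15, 15, 5))
  support <- array(FALSE, dim(I))
  support[4:12, 4:12, ] <- TRUE
  I[support] <- 50
  C <- estimate_background(I, c(5, 5, 3), passes = 1, support = support)
  expect_equal(C[support], rep(50, sum(support)))
})

test_that("binarization implements I > C(1 + thre) and is monotone", {
  I <- array(c(10, 7), c(2, 1, 1))
  C <- array(5, c(2, 1, 1))
  B <- binarize(I, C, 0.5)
  expect_equal(as.vector(B), c(TRUE, FALSE))   # 10 > 7.5, 7 < 7.5
  expect_equal(binarize(I, C, 0), I > C)
  set.seed(1)
  I2 <- array(runif(1000, 0, 10), c(10, 10, 10))
  C2 <- array(5, dim(I2))
  counts <- vapply(c(0, 0.2, 0.5, 1), function(th)
    sum(binarize(I2, C2, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(binarize(I2, C2, -1), ">= 0")
  expect_error(binarize(I2, array(0, c(2, 2, 2))), "shape")
})

test_that("erosion is anti-extensive and removes isolated voxels", {
  B <- array(FALSE, c(9, 9, 3))
  B[5, 5, 2] <- TRUE                  # isolated point
  B[2:8, 2, 1] <- TRUE                # a thin line (also eroded away)
  expect_false(any(erode_mask(B)[5, 5, 2]))
  set.seed(2)
  B2 <- array(runif(9 * 9 * 3) > 0.4, c(9, 9, 3))
  expect_true(all(erode_mask(B2) <= B2))
})

test_that("segment_foreground masks intensities and handles empty input", {
  set.seed(3)
  I <- array(rpois(20 * 20 * 6, 100), c(20, 20, 6))
  I[8:12, 8:12, 3] <- 900
  fg <- segment_foreground(I, template_size = c(9, 9, 3))
  expect_true(all(fg$foreground == I * fg$mask))
  expect_true(all(fg$foreground %in% c(0, I)))
  expect_true(all(fg$mask <= fg$mask_raw))
  expect_true(fg$mask[10, 10, 3])
  z <- segment_foreground(array(0, c(9, 9, 3)), template_size = c(3, 3, 3))
  expect_equal(sum(z$mask), 0)
  expect_equal(sum(z$foreground), 0)
})
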