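test_that("patch extraction centers the crop and sets the pixel pitch", {
  arr <- array(0, c(120, 120, 15))
  arr[61, 61, 8] <- 1000                      # voxel at (12, 12, 7) um
  vol <- bouton_volume(arr, c(0.2, 0.2, 1))
  p <- extract_patch(vol, c(12, 12, 7))
  expect_s3_class(p, "patch_sample")
  expect_equal(dim(p$image), c(240, 240))
  expect_equal(p$pixel_pitch_um, 0.05)
  bright <- which(p$image == max(p$image), arr.ind = TRUE)
  expect_lt(max(abs(bright[1, ] - c(119, 119))), 4)
  expect_equal(max(p$image), 1)               # min-max normalized
})

test_that("crops at the volume corner are zero-padded, not an error", {
  arr <- array(100, c(70, 70, 9))
  vol <- bouton_volume(arr, c(0.2, 0.2, 1))
  p <- extract_patch(vol, c(0, 0, 0), normalize = FALSE)
  expect_equal(dim(p$image), c(240, 240))
  expect_equal(p$image[1, 1], 0)              # padded region
  expect_gt(p$image[200, 200], 0)
  expect_error(extract_patch(vol, c(50, 50, 50)), "outside")
})

test_that("max projection of a z-constant volume equals a single plane", {
  set.seed(31)
  plane <- matrix(runif(60 * 60, 0, 5), 60)
  arr <- array(rep(plane, 7), c(60, 60, 7))
  vol <- bouton_volume(arr, c(0.2, 0.2, 1))
  p <- extract_patch(vol, c(5.8, 5.8, 3), upsample = 1, normalize = FALSE)
  expect_equal(p$image, plane)
})

test_that("augmentation families are label-preserving and deterministic", {
  set.seed(32)
  s <- structure(list(image = matrix(runif(64), 8), label = "bouton",
                      pixel_pitch_um = 0.05, source_center = c(0, 0, 0)),
                 class = "patch_sample")
  rot <- augment_samples(list(s), families = "rotation", seed = 1)
  expect_length(rot, 3L)
  expect_true(all(vapply(rot, function(r) r$label, "") == "bouton"))
  # 180-degree rotation applied twice is the identity
  r180 <- boutonfinder:::rot90(s$image, 2)
  expect_equal(boutonfinder:::rot90(r180, 2), s$image)
  # inverse shifts restore the interior
  sh <- boutonfinder:::shift_xy(boutonfinder:::shift_xy(s$image, 1, 1), -1, -1)
  expect_equal(sh[2:7, 2:7], s$image[2:7, 2:7])
  all5 <- augment_samples(list(s), seed = 9)
  expect_length(all5, 3 + 3 + 4 + 2 + 1)
  again <- augment_samples(list(s), seed = 9)
  expect_equal(all5, again)
})

test_that("the per-batch random transform is seed-deterministic", {
  stack <- array(runif(8 * 8 * 4), c(8, 8, 4))
  a <- withr::with_seed(5, random_patch_transform(stack))
  b <- withr::with_seed(5, random_patch_transform(stack))
  expect_equal(a, b)
  expect_equal(dim(a), dim(stack))
})
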