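test_that("voxel/um conversion follows the 0-based index times pitch rule", {
  pitch <- c(0.2, 0.2, 1)
  expect_equal(voxel_to_um(c(1, 1, 1), pitch), matrix(0, 1, 3))
  expect_equal(voxel_to_um(c(6, 11, 3), pitch), matrix(c(1, 2, 2), 1))
  idx <- cbind(sample(1:50, 20, TRUE), sample(1:50, 20, TRUE),
               sample(1:10, 20, TRUE))
  expect_equal(um_to_voxel(voxel_to_um(idx, pitch), pitch),
               unname(idx))
})

test_that("16-bit TIFF volumes round-trip through disk", {
  arr <- array(sample(0:5000, 24 * 20 * 5, TRUE), c(24, 20, 5))
  vol <- bouton_volume(arr, c(0.2, 0.2, 1))
  path <- withr::local_tempfile(fileext = ".tif")
  write_volume_tiff(vol, path)
  back <- read_volume_tiff(path, c(0.2, 0.2, 1))
  expect_equal(dim(back$data), dim(arr))
  expect_equal(back$data, arr, tolerance = 1e-8)
})

test_that("volume constructor validates inputs", {
  expect_error(bouton_volume(matrix(0, 3, 3)), "3D")
  expect_error(bouton_volume(array(0, c(2, 2, 2)), c(0.2, -1, 1)), "positive")
})
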