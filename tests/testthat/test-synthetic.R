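small_spec <- function(...) {
  scene_spec(dims = c(150L, 150L, 30L), axon_length_um = 80, ...)
}

test_that("identical seeds give byte-identical scene files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_scene(small_spec(), seed = 42, output_dir = d1)
  simulate_scene(small_spec(), seed = 42, output_dir = d2)
  for (f in c("volume.tif", "skeleton.swc", "truth.csv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 5e7),
                     readBin(file.path(d2, f), "raw", 5e7))
  }
  s3 <- simulate_scene(small_spec(), seed = 43)
  s1 <- simulate_scene(small_spec(), seed = 42)
  expect_false(identical(s1$volume$data, s3$volume$data))
})

test_that("swelling placement respects spacing, margins and the point rate", {
  spec <- scene_spec(bouton_density = 5, non_bouton_per_bouton = 1)
  counts <- integer(0)
  for (sd in 1:6) {
    tree <- simulate_axon_tree(spec, seed = sd)
    sw <- tree$swellings
    if (nrow(sw) >= 2) {
      expect_true(all(diff(sort(sw$s[sw$axon == 1])) >= 2 - 1e-9))
    }
    counts <- c(counts, sum(sw$class == "bouton"))
    expect_true(all(sw$width_ratio[sw$class == "bouton"] >= 2))
    expect_true(all(sw$width_ratio[sw$class == "non_bouton"] < 2))
  }
  # ~10 boutons expected per 200 um at 5 per 100 um (margins trim a few)
  expect_gt(mean(counts), 5)
  expect_lt(mean(counts), 14)
  expect_error(scene_spec(bouton_density = 30, non_bouton_per_bouton = 1),
               "spacing")
  expect_error(scene_spec(bouton_ratio_range = c(1.5, 3)), ">= 2")
  expect_error(scene_spec(non_bouton_ratio_range = c(1.2, 2.5)), "< 2")
})

test_that("planted classes obey the 2-fold width criterion when measured", {
  # widely spaced swellings so the flanking measurements are clean shaft
  spec <- small_spec(gaussian_sd = 0, poisson = FALSE, background = 0,
                     blur_um = c(0, 0, 0), turn_sd = 0.02,
                     bouton_density = 2, min_spacing_um = 8)
  found <- 0
  for (sd in 1:4) {
    scene <- simulate_scene(spec, seed = sd)
    tree <- simulate_axon_tree(spec, seed = sd)
    sw <- tree$swellings
    for (i in seq_len(nrow(sw))) {
      w_center <- measured_width_oracle(scene, tree$axons[[1]]$points, sw$s[i])
      flank <- mean(c(
        measured_width_oracle(scene, tree$axons[[1]]$points, sw$s[i] - 3),
        measured_width_oracle(scene, tree$axons[[1]]$points, sw$s[i] + 3)))
      if (flank <= 0) next
      found <- found + 1
      if (sw$class[i] == "bouton") {
        expect_gte(w_center / flank, 2 * 0.9)   # sampling tolerance
      } else {
        expect_lt(w_center / flank, 2 * 1.1)
      }
    }
  }
  expect_gt(found, 3)
})

test_that("truth points lie on the rendered axon and the SWC traces it", {
  scene <- simulate_scene(small_spec(), seed = 9)
  # every truth point carries bright signal well above background
  for (i in seq_len(nrow(scene$truth))) {
    v <- um_to_voxel(as.numeric(scene$truth[i, 1:3]), scene$volume$voxel_pitch)
    expect_gt(scene$volume$data[v[1], v[2], v[3]],
              3 * scene$spec$background)
  }
  # skeleton nodes sit on bright voxels too
  mid <- scene$skeleton[seq(5, nrow(scene$skeleton) - 5, by = 10), ]
  for (i in seq_len(nrow(mid))) {
    v <- um_to_voxel(c(mid$x[i], mid$y[i], mid$z[i]),
                     scene$volume$voxel_pitch)
    expect_gt(scene$volume$data[v[1], v[2], v[3]],
              2 * scene$spec$background)
  }
})

test_that("a zero-axon scene is background and noise only", {
  spec <- small_spec(n_axons = 0L)
  scene <- simulate_scene(spec, seed = 2)
  expect_equal(nrow(scene$truth), 0L)
  expect_lt(max(scene$volume$data), spec$background +
              10 * sqrt(spec$background) + 10 * spec$gaussian_sd)
})

test_that("training patch generation hits the requested class balance", {
  tp <- generate_training_patches(n = 21, seed = 3, positive_fraction = 0.5)
  tab <- table(tp$labels)
  expect_lte(abs(tab[["bouton"]] - tab[["non_bouton"]]), 1)
  expect_equal(dim(tp$images), c(60, 60, 21))
  tp2 <- generate_training_patches(n = 21, seed = 3)
  expect_equal(tp$images, tp2$images)
})
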