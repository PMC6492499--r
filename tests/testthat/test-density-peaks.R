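pitch <- c(0.2, 0.2, 1)

test_that("rho equals the brute-force Gaussian-weighted mean to 1e-10", {
  set.seed(11)
  F <- array(0, c(14, 14, 6))
  idx <- unique(cbind(sample(14, 60, TRUE), sample(14, 60, TRUE),
                      sample(6, 60, TRUE)))
  F[idx] <- runif(nrow(idx), 1, 10)
  mask <- F > 0
  ld <- local_density(F, sigma = 0.17, voxel_pitch = pitch, mask = mask)
  expect_lt(max(abs(ld$rho - rho_oracle(F, mask, 0.17, pitch))), 1e-10)
})

test_that("rho of a constant foreground is that constant", {
  F <- array(4.2, c(8, 8, 4))
  ld <- local_density(F, sigma = 0.3, voxel_pitch = pitch)
  expect_equal(ld$rho, rep(4.2, length(ld$rho)))
})

test_that("a single foreground voxel has rho equal to its own value", {
  F <- array(0, c(8, 8, 4)); F[3, 4, 2] <- 1
  ld <- local_density(F, sigma = 0.17, voxel_pitch = pitch)
  expect_equal(ld$rho, 1)
  expect_error(local_density(F, sigma = 0), "sigma")
})

test_that("delta matches hand values on the 1-D toy and brute force", {
  um3 <- cbind(c(0, 1, 10), 0, 0)
  md <- min_distance(um3, c(3, 2, 1), coords = cbind(c(1, 2, 11), 1, 1))
  expect_equal(md$delta, c(1, 0.1, 0.9))
  expect_equal(md$max_pairwise_distance, 10)
  expect_equal(min_distance(matrix(c(1, 1, 1), 1), 5)$delta, 1)
  set.seed(12)
  coords <- unique(cbind(sample(25, 200, TRUE), sample(25, 200, TRUE),
                         sample(8, 200, TRUE)))
  um <- sweep(coords - 1, 2, pitch, `*`)
  rho <- runif(nrow(coords))
  rho[sample(length(rho), 20)] <- 0.5   # force ties to exercise tie-breaks
  md <- min_distance(um, rho, coords = coords)
  expect_equal(md$delta, delta_oracle(um, rho, coords))
  expect_equal(sum(md$delta == 1), 1L)
  expect_true(all(md$delta > 0 & md$delta <= 1))
})

test_that("feature density is max-normalized, symmetric and near-exact", {
  lam <- feature_density(rep(2, 17), rep(0.3, 17))
  expect_equal(lam, rep(1, 17))
  set.seed(13)
  rho <- c(rnorm(100, 5, 0.2), 9)       # tight cluster plus one outlier
  delta <- c(abs(rnorm(100, 0.05, 0.01)), 0.9)
  lam <- feature_density(rho, delta)
  expect_equal(which.min(lam), 101L)
  perm <- sample(101)
  expect_equal(feature_density(rho[perm], delta[perm]), lam[perm])
  # binned evaluation tracks the exact kernel density estimate
  ex <- lambda_oracle(rho, delta, c(0.01, 0.02))
  expect_lt(max(abs(lam - ex)), 0.05)
})

test_that("the peak criterion reproduces the hand-evaluated toy", {
  um3 <- cbind(c(0, 1, 10), 0, 0)
  rho <- c(3, 2, 1)
  md <- min_distance(um3, rho, coords = cbind(c(1, 2, 11), 1, 1))
  fields <- list(coords = cbind(c(1, 2, 11), 1, 1), coords_um = um3,
                 rho = rho, delta = md$delta,
                 lambda = rep(0.5, 3),
                 max_pairwise_distance = md$max_pairwise_distance)
  peaks <- select_peaks(fields, thre_search = 1, R_min = 0.5,
                        min_rho_frac = 0)
  # delta * maxd = 10, 1, 9 um: all pass R_min = 0.5
  expect_equal(nrow(peaks), 3L)
  pd <- as.matrix(dist(peaks[, c("x_um", "y_um", "z_um")]))
  diag(pd) <- Inf
  expect_gte(min(pd), 0.5)
  # vanishing thre_search selects nothing
  expect_equal(nrow(select_peaks(fields, thre_search = 1e-12, R_min = 0.5)),
               0L)
})

test_that("two overlapping blobs 1.5 um apart are both recovered", {
  arr <- array(0, c(40, 40, 9))
  pk <- function(c_um, amp, sd) {
    idx <- which(array(TRUE, dim(arr)), arr.ind = TRUE)
    um <- sweep(idx - 1, 2, pitch, `*`)
    d2 <- colSums((t(um) - c_um)^2)
    amp * exp(-d2 / (2 * sd^2))
  }
  arr <- arr + pk(c(3, 4, 4), 100, 0.5) + pk(c(4.5, 4, 4), 80, 0.5)
  block <- bouton_volume(arr, pitch)
  cand <- detect_block(block, list(foreground = list(template_size = c(15, 15, 5)),
                                   detector = list(R_min = 0.4)))
  expect_gte(nrow(cand), 2L)
  d1 <- min(sqrt((cand$x_um - 3)^2 + (cand$y_um - 4)^2 + (cand$z_um - 4)^2))
  d2 <- min(sqrt((cand$x_um - 4.5)^2 + (cand$y_um - 4)^2 + (cand$z_um - 4)^2))
  expect_lt(d1, 0.3)
  expect_lt(d2, 0.3)
})

test_that("an empty block yields an empty candidate table", {
  blk <- bouton_volume(array(0, c(20, 20, 5)), pitch)
  cand <- detect_block(blk, list(foreground = list(template_size = c(9, 9, 3))))
  expect_equal(nrow(cand), 0L)
})

test_that("peaks on a second untraced fiber outside the tube are excluded", {
  scene <- simulate_scene(scene_spec(gaussian_sd = 0, poisson = FALSE,
                                     bouton_density = 3), seed = 5)
  # plant a bright blob 5 um off the traced centerline midpoint
  mid <- scene$skeleton[100, ]
  off <- um_to_voxel(c(mid$x, mid$y + 5, mid$z), pitch)
  d <- dim(scene$volume$data)
  if (all(off >= 1) && all(off <= d)) {
    scene$volume$data[off[1], off[2], off[3]] <- 60000
  }
  segs <- divide_tree(scene$skeleton)
  cands <- merge_candidates(lapply(segs, function(s)
    detect_block(extract_tube(scene$volume, s))))
  if (nrow(cands)) {
    dd <- sqrt((cands$x_um - mid$x)^2 + (cands$y_um - (mid$y + 5))^2 +
                 (cands$z_um - mid$z)^2)
    expect_gt(min(dd), 1.2)
  }
  succeed()
})
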