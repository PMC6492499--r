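test_that("greedy division covers a 300 um path with stride 90", {
  sk <- straight_skeleton(300)
  segs <- divide_tree(sk, segment_length = 100, overlap = 10)
  expect_length(segs, 4L)
  starts <- vapply(segs, function(s) min(s$x), numeric(1))
  # segments bracket their windows by at most one node on either side
  expect_equal(starts, c(0, 90, 180, 270), tolerance = 1.01)
  # consecutive segments share at least the overlap of centerline
  for (k in 1:3) {
    shared <- intersect(segs[[k]]$id, segs[[k + 1]]$id)
    xs <- sk$x[match(shared, sk$id)]
    expect_gte(diff(range(xs)), 10)
  }
})

test_that("a path shorter than the segment length yields one segment", {
  sk <- straight_skeleton(40)
  segs <- divide_tree(sk, segment_length = 100, overlap = 10)
  expect_length(segs, 1L)
  expect_setequal(segs[[1]]$id, sk$id)
})

test_that("every node of a branched tree is covered; branch points repeat", {
  # Y-shaped tree: trunk of 8 nodes, two branches of 6 each
  trunk <- data.frame(id = 1:8, type = 2L, x = 0:7, y = 0, z = 0,
                      radius = 0.3, parent = c(-1L, 1:7))
  b1 <- data.frame(id = 9:14, type = 2L, x = 7 + (1:6), y = (1:6), z = 0,
                   radius = 0.3, parent = c(8L, 9:13))
  b2 <- data.frame(id = 15:20, type = 2L, x = 7 + (1:6), y = -(1:6), z = 0,
                   radius = 0.3, parent = c(8L, 15:19))
  sk <- validate_skeleton_df(rbind(trunk, b1, b2))
  segs <- divide_tree(sk, segment_length = 5, overlap = 1)
  membership <- table(unlist(lapply(segs, `[[`, "id")))
  expect_setequal(as.integer(names(membership)), sk$id)
  # the branch point (node 8) starts both daughter paths and ends the trunk
  expect_gte(membership[["8"]], 3L)
  # interior overlap nodes belong to at least two segments of their path
  expect_gte(sum(membership >= 2L), 3L)
})

test_that("divide_tree validates arguments", {
  sk <- straight_skeleton(10)
  expect_error(divide_tree(sk, segment_length = 5, overlap = 5), "overlap")
  expect_error(divide_tree(sk[0, ], 100, 10), "empty skeleton")
})

test_that("tube mask equals the brute-force scaled-distance criterion", {
  vol <- bouton_volume(array(1, c(40, 40, 12)), c(0.2, 0.2, 1))
  sk <- straight_skeleton(4, origin = c(2, 4, 6))
  seg <- divide_tree(sk, 100, 10)[[1]]
  radii <- c(4, 4, 2)
  block <- extract_tube(vol, seg, tube_radii = radii)
  samples <- boutonfinder:::resample_polyline(
    as.matrix(seg[, c("x", "y", "z")]), 0.1)
  sv <- sweep(samples, 2, vol$voxel_pitch, `/`)   # 0-based voxel coords
  idx <- which(array(TRUE, dim(block$volume)), arr.ind = TRUE)
  gv <- sweep(idx - 1, 2, block$origin_offset, `+`)
  inside <- vapply(seq_len(nrow(gv)), function(i) {
    d <- sweep(sv, 2, gv[i, ])
    min(rowSums(sweep(-d, 2, radii, `/`)^2)) <= 1 + 1e-9
  }, logical(1))
  expect_equal(as.vector(block$tube_mask), inside)
  expect_true(all(block$volume[!block$tube_mask] == 0))
})

test_that("a single-node segment produces one ellipsoidal mask", {
  vol <- bouton_volume(array(1, c(40, 40, 12)), c(0.2, 0.2, 1))
  seg <- straight_skeleton(0, origin = c(4, 4, 6))[1, , drop = FALSE]
  class(seg) <- c("axon_segment", "data.frame")
  block <- extract_tube(vol, seg, tube_radii = c(8, 8, 4))
  ctr <- um_to_voxel(c(4, 4, 6), vol$voxel_pitch) - 1
  idx <- which(block$tube_mask, arr.ind = TRUE)
  gv <- sweep(idx - 1, 2, block$origin_offset, `+`)
  d2 <- colSums((sweep(t(gv), 1, as.numeric(ctr)) / c(8, 8, 4))^2)
  expect_true(all(d2 <= 1 + 1e-9))
  expect_gt(sum(block$tube_mask), 400)
})

test_that("an off-tube bright blob is excluded from the extracted volume", {
  arr <- array(0, c(100, 100, 20))
  arr[50, 25, 10] <- 1000   # 5 um in y from the centerline below
  vol <- bouton_volume(arr, c(0.2, 0.2, 1))
  sk <- straight_skeleton(16, origin = c(2, 10, 10))
  seg <- divide_tree(sk, 100, 10)[[1]]
  block <- extract_tube(vol, seg)       # tube radius 8 voxels = 1.6 um in y
  expect_equal(max(block$volume), 0)
  expect_error(extract_tube(bouton_volume(arr[1:10, 1:10, 1:2, drop = FALSE],
                                          c(0.2, 0.2, 1)),
                            divide_tree(straight_skeleton(5,
                              origin = c(50, 50, 50)), 100, 10)[[1]]),
               "outside")
})

test_that("merging keeps the densest representative and is idempotent", {
  a <- data.frame(x_um = 0.0, y_um = 0, z_um = 0, rho = 5, delta = 1,
                  lambda = 0, source_segment = 1L)
  b <- data.frame(x_um = 0.3, y_um = 0, z_um = 0, rho = 9, delta = 1,
                  lambda = 0, source_segment = 2L)
  m <- merge_candidates(list(a, b), merge_radius = 1.0)
  expect_equal(nrow(m), 1L)
  expect_equal(m$rho, 9)
  far <- data.frame(x_um = 2.0, y_um = 0, z_um = 0, rho = 1, delta = 1,
                    lambda = 0, source_segment = 1L)
  expect_equal(nrow(merge_candidates(list(a, far), merge_radius = 1.0)), 2L)
  # idempotence and order invariance on random candidates
  set.seed(7)
  cands <- data.frame(x_um = runif(100, 0, 20), y_um = runif(100, 0, 20),
                      z_um = runif(100, 0, 10), rho = runif(100),
                      delta = runif(100), lambda = 0,
                      source_segment = 1L)
  m1 <- merge_candidates(cands, merge_radius = 1.5)
  expect_equal(merge_candidates(m1, merge_radius = 1.5), m1)
  m2 <- merge_candidates(cands[sample(nrow(cands)), ], merge_radius = 1.5)
  expect_equal(m1[order(m1$x_um), ], m2[order(m2$x_um), ],
               ignore_attr = TRUE)
  pd <- as.matrix(dist(m1[, c("x_um", "y_um", "z_um")]))
  diag(pd) <- Inf
  expect_gte(min(pd), 1.5)
  expect_equal(nrow(merge_candidates(list())), 0L)
})
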