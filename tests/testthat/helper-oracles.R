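# Independent brute-force oracles used to check the optimized field
# computations. These deliberately re-derive everything from the defining
# formulas with plain O(n^2) loops.

# Gaussian-weighted mean density over a spherical window (weighted-mean
# normalization).
rho_oracle <- function(F, mask, sigma, pitch, R = 2 * sigma) {
  coords <- which(mask, arr.ind = TRUE)
  um <- sweep(coords - 1, 2, pitch, `*`)
  vals <- F[coords]
  vapply(seq_len(nrow(coords)), function(i) {
    d2 <- colSums((t(um) - um[i, ])^2)
    inwin <- sqrt(d2) <= R + 1e-12
    w <- exp(-d2 / (2 * sigma^2))
    sum(w[inwin] * vals[inwin]) / sum(w[inwin])
  }, numeric(1))
}

# Normalized minimum distance to a strictly denser point, ties broken by
# lexicographically smaller (z, y, x) voxel index counting as denser.
delta_oracle <- function(um, rho, coords) {
  n <- nrow(um)
  if (n == 1L) return(1)
  ord <- order(-rho, coords[, 3], coords[, 2], coords[, 1])
  rank <- match(seq_len(n), ord)
  D <- as.matrix(stats::dist(um))
  maxd <- max(D)
  vapply(seq_len(n), function(i) {
    denser <- which(rank < rank[i])
    if (!length(denser)) return(1)
    min(D[i, denser]) / maxd
  }, numeric(1))
}

# Exact 2D Gaussian KDE in the (rho_hat, delta) plane, max-normalized.
lambda_oracle <- function(rho, delta, bandwidth) {
  bandwidth <- rep_len(bandwidth, 2L)
  rng <- range(rho)
  rho_hat <- if (rng[2] > rng[1]) (rho - rng[1]) / diff(rng) else rho * 0
  lam <- vapply(seq_along(rho), function(i) {
    sum(exp(-(rho_hat - rho_hat[i])^2 / (2 * bandwidth[1]^2)
            - (delta - delta[i])^2 / (2 * bandwidth[2]^2)))
  }, numeric(1))
  lam / max(lam)
}

# Maximum-cardinality one-to-one matching within tolerance (augmenting-path
# bipartite matching): the optimal number of matched pairs.
max_matching_oracle <- function(gt, det, tolerance) {
  gt <- as.matrix(gt); det <- as.matrix(det)
  if (nrow(gt) == 0L || nrow(det) == 0L) return(0L)
  D <- sqrt(pmax(outer(rowSums(gt^2), rowSums(det^2), `+`) -
                   2 * gt %*% t(det), 0))
  adj <- D <= tolerance + 1e-9
  match_of <- rep(0L, nrow(det))
  try_augment <- function(g, seen) {
    for (d in which(adj[g, ])) {
      if (seen[d]) next
      seen[d] <- TRUE
      if (match_of[d] == 0L) {
        match_of[d] <<- g
        return(TRUE)
      }
      old <- match_of[d]
      match_of[d] <<- g
      res <- try_augment(old, seen)
      if (res) return(TRUE)
      match_of[d] <<- old
    }
    FALSE
  }
  total <- 0L
  for (g in seq_len(nrow(gt))) {
    if (try_augment(g, rep(FALSE, nrow(det)))) total <- total + 1L
  }
  total
}

# Measure the apparent full width (FWHM, um) of the rendered tube in the
# xy max-projection, along the in-plane normal of the centerline at
# arclength s.
measured_width_oracle <- function(scene, axon_pts, s_um) {
  proj <- apply(scene$volume$data, c(1, 2), max)
  pitch <- scene$volume$voxel_pitch[1:2]
  seg <- sqrt(rowSums(diff(axon_pts)^2))
  cs <- c(0, cumsum(seg))
  i <- findInterval(s_um, cs, all.inside = TRUE)
  t <- (s_um - cs[i]) / max(seg[i], 1e-12)
  center <- axon_pts[i, ] + t * (axon_pts[i + 1, ] - axon_pts[i, ])
  dirv <- axon_pts[i + 1, 1:2] - axon_pts[i, 1:2]
  dirv <- dirv / sqrt(sum(dirv^2))
  normal <- c(-dirv[2], dirv[1])
  offs <- seq(-2, 2, by = 0.02)
  d <- dim(proj)
  prof <- vapply(offs, function(o) {
    p <- center[1:2] + o * normal
    ij <- p / pitch + 1     # continuous pixel position, bilinear lookup
    i0 <- floor(ij)
    if (any(i0 < 1) || i0[1] >= d[1] || i0[2] >= d[2]) return(0)
    f <- ij - i0
    proj[i0[1], i0[2]] * (1 - f[1]) * (1 - f[2]) +
      proj[i0[1] + 1, i0[2]] * f[1] * (1 - f[2]) +
      proj[i0[1], i0[2] + 1] * (1 - f[1]) * f[2] +
      proj[i0[1] + 1, i0[2] + 1] * f[1] * f[2]
  }, numeric(1))
  half <- max(prof) / 2
  above <- which(prof >= half)
  if (!length(above)) return(0)
  (max(above) - min(above)) * 0.02
}

# A small straight-path skeleton along +x, nodes every `step` um.
straight_skeleton <- function(length_um, step = 1, origin = c(0, 0, 0)) {
  n <- round(length_um / step) + 1L
  validate_skeleton_df(data.frame(
    id = seq_len(n), type = 2L,
    x = origin[1] + (seq_len(n) - 1) * step, y = origin[2], z = origin[3],
    radius = 0.25, parent = c(-1L, seq_len(n - 1L))))
}

validate_skeleton_df <- function(df) {
  class(df) <- c("neuron_skeleton", "data.frame")
  df
}
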