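#' Local signal density of foreground voxels
#'
#' For each foreground voxel the local density `rho` is the Gaussian-weighted
#' mean of foreground intensities within a spherical window of radius
#' `R = 2 * sigma` (physical micrometres, so the axial anisotropy of the
#' voxel grid is respected):
#' \deqn{\rho_i = \frac{1}{Z_i} \sum_{\|p_i - p_j\| \le R} I(p_j)
#'   \exp\!\left(-\frac{\|p_i - p_j\|^2}{2\sigma^2}\right)}
#' with, by default, `Z_i` the sum of the Gaussian weights over the same
#' window (a weighted mean, so a constant image has constant `rho`). The
#' kernel width `sigma` should be about one third of the average bouton
#' radius.
#'
#' @param F foreground intensity 3D array (zero outside the foreground).
#' @param sigma Gaussian kernel width, micrometres.
#' @param voxel_pitch micrometres per voxel (x, y, z).
#' @param mask optional logical array marking foreground voxels; defaults to
#'   `F > 0`.
#' @param R window radius, micrometres; default `2 * sigma`.
#' @param normalization `"window"` (weighted mean, default) or `"constant"`
#'   (fixed normalization `1/(sqrt(2 pi) sigma)`, a plain kernel sum).
#' @return list with `coords` (n x 3 voxel indices, 1-based), `coords_um`
#'   (n x 3 micrometres), and `rho` (length n).
#' @export
local_density <- function(F, sigma, voxel_pitch = c(0.2, 0.2, 1),
                          mask = NULL, R = 2 * sigma,
                          normalization = c("window", "constant")) {
  if (sigma <= 0) stop("sigma must be > 0")
  normalization <- match.arg(normalization)
  if (is.null(mask)) mask <- F > 0
  coords <- which(mask, arr.ind = TRUE)
  if (nrow(coords) == 0L) {
    return(list(coords = coords, coords_um = coords, rho = numeric(0)))
  }
  rho <- .rho_field_cpp(F, dim(F), coords - 1L, voxel_pitch, sigma, R,
                        if (normalization == "window") 0L else 1L)
  list(coords = coords, coords_um = voxel_to_um(coords, voxel_pitch),
       rho = rho)
}

#' Normalized minimum distance to a denser voxel
#'
#' For each foreground voxel, `delta` is the distance to the nearest voxel of
#' strictly higher density, normalized by the maximum pairwise distance among
#' all foreground voxels; the global density maximum gets `delta = 1`.
#' Density ties are broken by lexicographically smaller voxel index
#' `(z, y, x)` counting as "denser", so `delta` is well defined on intensity
#' plateaus and exactly one voxel per block receives `delta = 1`.
#'
#' @param coords_um n x 3 matrix of foreground voxel positions, micrometres.
#' @param rho densities from [local_density()].
#' @param coords n x 3 matrix of voxel indices (used only for tie-breaking);
#'   defaults to `coords_um` rounded to a grid.
#' @param cell spatial binning cell size (micrometres) for the neighbor
#'   search; affects speed only, not the result.
#' @return list with `delta` (normalized, in `(0, 1]`) and
#'   `max_pairwise_distance` (micrometres).
#' @export
min_distance <- function(coords_um, rho, coords = NULL, cell = 1.0) {
  coords_um <- rbind2mat(coords_um)
  n <- nrow(coords_um)
  if (n == 0L) return(list(delta = numeric(0), max_pairwise_distance = 0))
  if (is.null(coords)) coords <- round(coords_um * 1e6)
  storage.mode(coords) <- "integer"
  if (n == 1L) return(list(delta = 1, max_pairwise_distance = 0))
  maxd <- .max_pairwise_cpp(coords_um)
  raw <- .delta_field_cpp(coords_um, coords, rho, cell)
  delta <- raw / maxd
  delta[is.na(raw)] <- 1
  list(delta = delta, max_pairwise_distance = maxd)
}

#' Feature-space density in the (rho, delta) plane
#'
#' Swelling centers have simultaneously high density and a large distance to
#' any denser voxel, so they sit isolated in the `(rho, delta)` scatter while
#' ordinary axonal voxels pile up along the low-`delta` band. `Lambda`
#' estimates the density of that scatter with a Gaussian kernel density
#' estimate (`rho` rescaled to `[0, 1]`), normalized so that
#' `max(Lambda) = 1`; candidate peaks are the points with low `Lambda`. The
#' KDE is evaluated on a fine grid with bilinear interpolation back to the
#' points, which is deterministic and independent of input order.
#'
#' The bandwidth may differ per axis: a narrow `rho` bandwidth keeps
#' noise-induced local maxima (which share the bulk axon intensity) inside
#' the dense cloud, while a wider `delta` bandwidth tolerates the very
#' compressed normalized-distance axis.
#'
#' @param rho,delta fields from [local_density()] and [min_distance()].
#' @param bandwidth Gaussian kernel bandwidth(s) in the unit square: a
#'   single value or `c(rho_bandwidth, delta_bandwidth)`.
#' @param grid_size number of KDE grid bins per axis.
#' @return numeric vector `lambda` in `(0, 1]`, `max(lambda) == 1`.
#' @export
feature_density <- function(rho, delta, bandwidth = c(0.01, 0.02),
                            grid_size = 256L) {
  n <- length(rho)
  if (n == 0L) return(numeric(0))
  bandwidth <- rep_len(bandwidth, 2L)
  rng <- range(rho)
  rho_hat <- if (rng[2] > rng[1]) (rho - rng[1]) / (rng[2] - rng[1]) else
    rep(0, n)
  g <- (seq_len(grid_size) - 0.5) / grid_size   # bin centers in [0, 1]
  bx <- pmin(pmax(ceiling(rho_hat * grid_size), 1L), grid_size)
  by <- pmin(pmax(ceiling(delta * grid_size), 1L), grid_size)
  H <- matrix(0, grid_size, grid_size)
  tab <- table(factor(bx, levels = seq_len(grid_size)),
               factor(by, levels = seq_len(grid_size)))
  H[] <- as.numeric(tab)
  Kr <- exp(-outer(g, g, `-`)^2 / (2 * bandwidth[1]^2))
  Kd <- exp(-outer(g, g, `-`)^2 / (2 * bandwidth[2]^2))
  S <- Kr %*% H %*% Kd                            # KDE at bin centers
  lam <- interp_bilinear(S, rho_hat * grid_size + 0.5, delta * grid_size + 0.5)
  lam / max(lam)
}

# Bilinear interpolation of matrix M at continuous (i, j) positions given in
# bin units (bin centers at 1..n).
interp_bilinear <- function(M, i, j) {
  n1 <- nrow(M); n2 <- ncol(M)
  i <- pmin(pmax(i, 1), n1); j <- pmin(pmax(j, 1), n2)
  i0 <- pmin(floor(i), n1 - 1); j0 <- pmin(floor(j), n2 - 1)
  fi <- i - i0; fj <- j - j0
  M[cbind(i0, j0)] * (1 - fi) * (1 - fj) + M[cbind(i0 + 1, j0)] * fi * (1 - fj) +
    M[cbind(i0, j0 + 1)] * (1 - fi) * fj + M[cbind(i0 + 1, j0 + 1)] * fi * fj
}

#' Select density peaks as bouton candidates
#'
#' A voxel is a candidate swelling center when it has higher local density
#' than every voxel in its 26-neighborhood (a swelling center is denser than
#' its neighbors; in particular a voxel whose axial neighbor is denser is a
#' mere cross-section of that structure, not a center), is isolated in the
#' `(rho, delta)` plane (`lambda <= thre_search`), and is far enough from
#' every denser voxel (`delta >= R_min / max_pairwise_distance`, with
#' `R_min` the minimum estimated bouton radius). Any two selected peaks are
#' automatically at least `R_min` apart, because the lower-density peak's
#' `delta` bounds its distance to every denser voxel.
#'
#' @param fields list with `coords`, `coords_um`, `rho`, `delta`, `lambda`,
#'   `max_pairwise_distance` (see [detect_block()] for assembly).
#' @param thre_search feature-density threshold in `(0, 1]`, default 0.2.
#' @param R_min minimum estimated bouton radius, micrometres, default 0.4.
#' @param min_rho_frac floor on the candidate's density relative to the
#'   block's density range (default 0.08): centers must carry appreciable
#'   signal, which suppresses dim noise-induced maxima along the axon
#'   shaft.
#' @return candidate data frame with columns `x_um`, `y_um`, `z_um`, `rho`,
#'   `delta`, `lambda`, `source_segment`.
#' @export
select_peaks <- function(fields, thre_search = 0.2, R_min = 0.4,
                         min_rho_frac = 0.08) {
  stopifnot(thre_search > 0, thre_search <= 1, R_min > 0)
  n <- length(fields$rho)
  if (n == 0L) return(empty_candidates())
  maxd <- fields$max_pairwise_distance
  rho_hat <- (fields$rho - min(fields$rho)) /
    max(diff(range(fields$rho)), 1e-12)
  ok <- fields$lambda <= thre_search &
    (if (maxd > 0) fields$delta >= R_min / maxd else fields$delta >= 1) &
    rho_hat >= min_rho_frac
  if (!is.null(fields$local_max)) ok <- ok & fields$local_max
  out <- data.frame(x_um = fields$coords_um[ok, 1],
                    y_um = fields$coords_um[ok, 2],
                    z_um = fields$coords_um[ok, 3],
                    rho = fields$rho[ok], delta = fields$delta[ok],
                    lambda = fields$lambda[ok],
                    source_segment = rep(fields$source_segment %||% NA_integer_,
                                         sum(ok)))
  rownames(out) <- NULL
  out
}

#' Detect candidate swelling centers in a sub-block
#'
#' Composes foreground segmentation, the density field `rho`, the normalized
#' minimum distance `delta`, the feature density `lambda`, and peak
#' selection, restricted to the sub-block's tube mask; candidate coordinates
#' are reported in global micrometres of the parent volume.
#'
#' @param block a `sub_block` from [extract_tube()] (or a [bouton_volume()],
#'   in which case no tube restriction applies).
#' @param params detector parameter list; see [default_config()] sections
#'   `foreground` and `detector`.
#' @return candidate data frame as in [select_peaks()].
#' @export
detect_block <- function(block, params = list()) {
  p <- modifyList(default_config()[c("foreground", "detector")], params)
  if (inherits(block, "bouton_volume")) {
    block <- structure(list(volume = block$data,
                            tube_mask = array(TRUE, dim(block$data)),
                            origin_offset = c(0L, 0L, 0L),
                            voxel_pitch = block$voxel_pitch,
                            segment_index = NA_integer_),
                       class = "sub_block")
  }
  fg <- segment_foreground(block$volume,
                           template_size = p$foreground$template_size,
                           passes = p$foreground$passes,
                           thre_binarization = p$foreground$thre_binarization,
                           erosion_iterations = p$foreground$erosion_iterations,
                           support = block$tube_mask)
  mask <- fg$mask & block$tube_mask
  if (!any(mask)) return(empty_candidates())
  F <- block$volume * mask
  ld <- local_density(F, sigma = p$detector$sigma,
                      voxel_pitch = block$voxel_pitch, mask = mask,
                      normalization = p$detector$normalization)
  lmax <- .local_max_cpp(dim(F), ld$coords - 1L, ld$rho)
  md <- min_distance(ld$coords_um, ld$rho, coords = ld$coords)
  lam <- feature_density(ld$rho, md$delta,
                         bandwidth = p$detector$kde_bandwidth,
                         grid_size = p$detector$kde_grid)
  fields <- list(coords = ld$coords,
                 coords_um = sweep(ld$coords_um, 2,
                                   block$origin_offset * block$voxel_pitch,
                                   `+`),
                 rho = ld$rho, delta = md$delta, lambda = lam,
                 local_max = lmax,
                 max_pairwise_distance = md$max_pairwise_distance,
                 source_segment = block$segment_index)
  select_peaks(fields, thre_search = p$detector$thre_search,
               R_min = p$detector$R_min,
               min_rho_frac = p$detector$min_rho_frac)
}
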