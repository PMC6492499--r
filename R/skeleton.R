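#' Divide a traced neuron tree into overlapping axonal segments
#'
#' The arbor is decomposed into unbranched paths (between roots, branch points
#' and tips) and each path is covered greedily by segments of at most
#' `segment_length` micrometres of centerline, advancing with stride
#' `segment_length - overlap` so that consecutive segments share at least
#' `overlap` micrometres. Branch points terminate every incident path and are
#' therefore contained in every segment touching them. The overlap should
#' exceed one bouton diameter so that no bouton straddles an uncovered seam.
#'
#' @param skeleton a `neuron_skeleton` from [read_swc()].
#' @param segment_length target centerline length per segment, micrometres.
#' @param overlap centerline length shared by consecutive segments,
#'   micrometres; must satisfy `0 <= overlap < segment_length`.
#' @param axon_only if `TRUE`, restrict to nodes with SWC structure code 2
#'   (axon) before division; by default all nodes are treated as axon.
#' @return list of `axon_segment` objects: data frames of ordered nodes
#'   (columns of the skeleton plus `s`, the arclength along the segment's
#'   path), with attributes `segment_index` and `overlap_length`.
#' @export
divide_tree <- function(skeleton, segment_length = 100, overlap = 10,
                        axon_only = FALSE) {
  stopifnot(inherits(skeleton, "neuron_skeleton"))
  if (!(segment_length > overlap && overlap >= 0)) {
    stop("need segment_length > overlap >= 0")
  }
  nodes <- skeleton
  if (axon_only) {
    keep <- nodes$type == 2L
    # keep parents of axon nodes so paths stay connected to their origin
    keep <- keep | nodes$id %in% nodes$parent[keep]
    nodes <- nodes[keep, , drop = FALSE]
    nodes$parent[!(nodes$parent %in% nodes$id)] <- -1L
  }
  if (nrow(nodes) == 0L) stop("empty skeleton: nothing to divide")
  paths <- tree_paths(nodes)
  segs <- list()
  stride <- segment_length - overlap
  for (p in paths) {
    pts <- as.matrix(nodes[match(p, nodes$id), c("x", "y", "z")])
    s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
    total <- s[length(s)]
    n_seg <- if (total <= segment_length) 1L else
      as.integer(ceiling((total - segment_length) / stride)) + 1L
    for (k in seq_len(n_seg)) {
      s0 <- (k - 1) * stride
      s1 <- min(s0 + segment_length, total)
      inside <- which(s >= s0 - 1e-9 & s <= s1 + 1e-9)
      lo <- max(min(inside) - 1L, 1L)          # bracket so geometry spans
      hi <- min(max(inside) + 1L, length(s))   # the whole [s0, s1] window
      idx <- lo:hi
      seg <- nodes[match(p[idx], nodes$id), , drop = FALSE]
      seg$s <- s[idx] - s[idx[1]]
      rownames(seg) <- NULL
      class(seg) <- c("axon_segment", "data.frame")
      attr(seg, "segment_index") <- length(segs) + 1L
      attr(seg, "overlap_length") <- overlap
      segs[[length(segs) + 1L]] <- seg
    }
  }
  segs
}

# Decompose a tree (parent-pointer form) into unbranched paths whose
# endpoints are roots, branch points or tips. Single-node components yield a
# one-node path.
tree_paths <- function(nodes) {
  id <- nodes$id
  parent <- nodes$parent
  children <- split(id[parent >= 0], factor(parent[parent >= 0], levels = id))
  n_children <- lengths(children)
  names(n_children) <- as.character(id)
  is_root <- parent < 0
  is_break <- is_root | n_children >= 2L   # path starts
  paths <- list()
  for (start in id[is_break]) {
    kids <- children[[as.character(start)]]
    if (length(kids) == 0L && is_root[match(start, id)]) {
      paths[[length(paths) + 1L]] <- start  # isolated root
      next
    }
    for (k in kids) {
      path <- c(start, k)
      cur <- k
      repeat {
        nxt <- children[[as.character(cur)]]
        if (length(nxt) != 1L) break        # tip or branch point: stop
        cur <- nxt
        path <- c(path, cur)
      }
      paths[[length(paths) + 1L]] <- path
    }
  }
  paths
}

#' Extract the tubular sub-volume around an axonal segment
#'
#' Resamples the segment centerline at half the smallest voxel pitch, marks
#' every voxel whose anisotropically scaled offset from some centerline sample
#' lies inside the ellipsoid (or box) with the given per-axis radii, crops the
#' bounding box of that tube mask, and zeroes all intensities outside the
#' tube. This restricts all downstream detection to the traced neuron's own
#' signal, so fibers of other cells passing nearby are excluded.
#'
#' @param volume a [bouton_volume()].
#' @param segment an `axon_segment` from [divide_tree()] (coordinates in
#'   micrometres in the volume frame).
#' @param tube_radii per-axis tube radius in voxels, default `c(8, 8, 4)`.
#' @param shape `"ellipsoid"` (default) or `"box"` neighborhood around each
#'   centerline sample.
#' @return a `sub_block`: list with `volume` (cropped, zeroed outside tube),
#'   `tube_mask` (logical array, same shape), `origin_offset` (0-based voxel
#'   index of the crop in the parent volume), `voxel_pitch`, and
#'   `segment_index`.
#' @export
extract_tube <- function(volume, segment, tube_radii = c(8, 8, 4),
                         shape = c("ellipsoid", "box")) {
  stopifnot(inherits(volume, "bouton_volume"))
  shape <- match.arg(shape)
  d <- dim(volume$data)
  pitch <- volume$voxel_pitch
  pts <- as.matrix(segment[, c("x", "y", "z")])
  samples <- resample_polyline(pts, 0.5 * min(pitch))
  # continuous 0-based voxel coordinates of the centerline samples
  cv <- sweep(samples, 2, pitch, `/`)
  inb <- cv[, 1] > -tube_radii[1] & cv[, 1] < d[1] - 1 + tube_radii[1] &
         cv[, 2] > -tube_radii[2] & cv[, 2] < d[2] - 1 + tube_radii[2] &
         cv[, 3] > -tube_radii[3] & cv[, 3] < d[3] - 1 + tube_radii[3]
  if (!any(inb)) stop("segment lies entirely outside the volume")
  cv <- cv[inb, , drop = FALSE]
  off <- as.matrix(expand.grid(x = -ceiling(tube_radii[1]):ceiling(tube_radii[1]),
                               y = -ceiling(tube_radii[2]):ceiling(tube_radii[2]),
                               z = -ceiling(tube_radii[3]):ceiling(tube_radii[3])))
  mask <- array(FALSE, d)
  for (i in seq_len(nrow(cv))) {
    base <- round(cv[i, ])
    frac <- cv[i, ] - base
    vox <- sweep(off, 2, base, `+`)                  # 0-based voxel indices
    rel <- sweep(off, 2, frac, `-`)                  # offset from true center
    inside <- if (shape == "ellipsoid") {
      (rel[, 1] / tube_radii[1])^2 + (rel[, 2] / tube_radii[2])^2 +
        (rel[, 3] / tube_radii[3])^2 <= 1
    } else {
      abs(rel[, 1]) <= tube_radii[1] & abs(rel[, 2]) <= tube_radii[2] &
        abs(rel[, 3]) <= tube_radii[3]
    }
    ok <- inside & vox[, 1] >= 0 & vox[, 1] < d[1] &
      vox[, 2] >= 0 & vox[, 2] < d[2] & vox[, 3] >= 0 & vox[, 3] < d[3]
    if (any(ok)) {
      lin <- vox[ok, 1] + d[1] * (vox[ok, 2] + d[2] * vox[ok, 3]) + 1
      mask[lin] <- TRUE
    }
  }
  if (!any(mask)) stop("segment lies entirely outside the volume")
  rng <- apply(which(mask, arr.ind = TRUE), 2, range)
  crop_mask <- mask[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
                    rng[1, 3]:rng[2, 3], drop = FALSE]
  crop_vol <- volume$data[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
                          rng[1, 3]:rng[2, 3], drop = FALSE]
  crop_vol[!crop_mask] <- 0
  structure(list(volume = crop_vol, tube_mask = crop_mask,
                 origin_offset = rng[1, ] - 1L, voxel_pitch = pitch,
                 segment_index = attr(segment, "segment_index") %||% NA_integer_),
            class = "sub_block")
}

# Resample a polyline (n x 3, um) at approximately `step` um spacing,
# keeping the original vertices.
resample_polyline <- function(pts, step) {
  if (nrow(pts) == 1L) return(pts)
  out <- list(pts[1, , drop = FALSE])
  for (i in seq_len(nrow(pts) - 1L)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    n <- max(1L, ceiling(len / step))
    t <- seq_len(n) / n
    out[[i + 1L]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]),
                           a[3] + t * (b[3] - a[3]))
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Merge duplicate candidates from overlapping segments
#'
#' Candidates from redundant segments can describe the same swelling twice.
#' Candidates are ranked by decreasing local density `rho` (ties broken by
#' lexicographically smallest `(z, y, x)`) and kept greedily: a candidate is
#' dropped if a kept candidate lies within `merge_radius` micrometres. The
#' result has minimum pairwise distance `>= merge_radius`, keeps the
#' highest-`rho` representative of each duplicate group, and the operation is
#' idempotent and independent of input order.
#'
#' @param candidates a candidate data frame (columns `x_um`, `y_um`, `z_um`,
#'   `rho`, ...) or a list of such data frames (one per segment).
#' @param merge_radius micrometres; duplicates closer than this are merged.
#' @return a single merged candidate data frame.
#' @export
merge_candidates <- function(candidates, merge_radius = 1.2) {
  if (is.data.frame(candidates)) candidates <- list(candidates)
  all <- do.call(rbind, candidates)
  if (is.null(all) || nrow(all) == 0L) return(empty_candidates())
  ord <- order(-all$rho, all$z_um, all$y_um, all$x_um)
  all <- all[ord, , drop = FALSE]
  pts <- as.matrix(all[, c("x_um", "y_um", "z_um")])
  keep <- logical(nrow(all))
  for (i in seq_len(nrow(all))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    dmin <- min(sqrt(colSums((t(pts[keep, , drop = FALSE]) - pts[i, ])^2)))
    if (dmin >= merge_radius) keep[i] <- TRUE
  }
  out <- all[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_candidates <- function() {
  data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
             rho = numeric(0), delta = numeric(0), lambda = numeric(0),
             source_segment = integer(0))
}
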