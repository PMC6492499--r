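#' Estimate a smooth background image by repeated average filtering
#'
#' The background `C` is the input convolved `passes` times with a uniform
#' averaging template of size `template_size` voxels (separable box filter).
#' Borders are handled by replicating the edge values, which avoids dark
#' halos that would spuriously binarize block borders. The template should be
#' larger than any bouton so that boutons do not inflate their own local
#' background.
#'
#' When a `support` mask is given (e.g. the tubular extraction mask of a
#' sub-block, whose outside voxels are zeroed and carry no signal), the
#' average is a normalized convolution restricted to the supported voxels:
#' each pass computes `box(C * support) / box(support)`, so the zeros
#' outside the support do not drag the background estimate down.
#'
#' @param I numeric 3D array of intensities.
#' @param template_size odd template size per axis (voxels), default
#'   `c(21, 21, 5)` (about 4 x 4 x 5 um at 0.2 x 0.2 x 1 um pitch).
#' @param passes number of filtering passes (>= 1), default 3.
#' @param support optional logical array: voxels carrying valid signal.
#' @return background array `C`, same shape as `I` (meaningful on the
#'   support; 0 where the smoothed support weight vanishes).
#' @export
estimate_background <- function(I, template_size = c(21, 21, 5), passes = 3,
                                support = NULL) {
  stopifnot(length(dim(I)) == 3L, passes >= 1)
  template_size <- rep_len(as.integer(template_size), 3L)
  if (any(template_size %% 2L == 0L)) stop("template_size must be odd per axis")
  if (any(template_size > dim(I))) {
    stop("averaging template larger than the volume")
  }
  box <- function(A) {
    for (ax in 1:3) {
      k <- template_size[ax]
      if (k > 1L) A <- filter_axis(A, rep(1 / k, k), ax)
    }
    A
  }
  if (is.null(support)) {
    C <- I
    for (p in seq_len(passes)) C <- box(C)
  } else {
    M <- array(as.numeric(support), dim(I))
    W <- box(M)
    C <- I
    for (p in seq_len(passes)) {
      C <- box(C * M) / pmax(W, 1e-12)
      C[W <= 1e-12] <- 0
    }
  }
  C
}

# Convolve a 3D array along one axis with an odd-length symmetric kernel,
# replicating edge values: bring the axis first, pad, and correlate each
# column (correlation equals convolution for the symmetric kernels used).
filter_axis <- function(A, kernel, axis) {
  d <- dim(A)
  h <- (length(kernel) - 1L) %/% 2L
  perm <- c(axis, setdiff(1:3, axis))
  B <- aperm(A, perm)
  db <- dim(B)
  M <- matrix(B, nrow = db[1])
  Mp <- rbind(M[rep(1L, h), , drop = FALSE], M,
              M[rep(db[1], h), , drop = FALSE])
  out <- array(.filter_cols_cpp(Mp, kernel), db)
  aperm(out, order(perm))
}

#' Adaptive binarization against a background estimate
#'
#' A voxel is foreground when its intensity exceeds the local background by a
#' relative margin: `B = 1` iff `I > C + thre_binarization * C`, i.e.
#' `I > C * (1 + thre_binarization)`. Raising the threshold never adds
#' foreground voxels.
#'
#' @param I intensity array.
#' @param C background array from [estimate_background()], same shape.
#' @param thre_binarization non-negative relative threshold, default 0.3.
#' @return logical array `B`, same shape as `I`.
#' @export
binarize <- function(I, C, thre_binarization = 0.3) {
  if (!identical(dim(I), dim(C))) stop("I and C must have the same shape")
  if (thre_binarization < 0) stop("thre_binarization must be >= 0")
  I > C * (1 + thre_binarization)
}

#' Mild morphological erosion of a binary mask, per z-plane
#'
#' Erosion with an in-plane 4-connected cross element removes isolated noise
#' voxels while preserving tubular structures. It is applied in 2D per
#' z-plane because the axial pitch of the target datasets is several times
#' coarser than the lateral pitch; an isotropic 3D erosion at that anisotropy
#' would sever thin axons. Values beyond the block border are treated as
#' replicated, so structures touching the border are not artificially eroded.
#'
#' @param B logical 3D array.
#' @param iterations number of erosion passes, default 1 ("mild").
#' @return eroded logical array, a subset of `B`.
#' @export
erode_mask <- function(B, iterations = 1) {
  d <- dim(B)
  for (it in seq_len(iterations)) {
    sxm <- B[c(1L, seq_len(d[1] - 1L)), , , drop = FALSE]
    sxp <- B[c(seq_len(d[1] - 1L) + 1L, d[1]), , , drop = FALSE]
    sym <- B[, c(1L, seq_len(d[2] - 1L)), , drop = FALSE]
    syp <- B[, c(seq_len(d[2] - 1L) + 1L, d[2]), , drop = FALSE]
    B <- B & sxm & sxp & sym & syp
  }
  B
}

#' Segment foreground signal from a sub-block
#'
#' Composes [estimate_background()], [binarize()] and [erode_mask()] and
#' returns the masked intensity image `F = I * B` used by the density-peak
#' detector. The defaults are deliberately permissive so that essentially all
#' underlying bouton regions survive segmentation; the classifier stage, not
#' the segmentation, is responsible for specificity.
#'
#' @param I intensity 3D array (or a `sub_block`, whose tube mask is then
#'   intersected with the foreground mask).
#' @param template_size,passes see [estimate_background()].
#' @param thre_binarization see [binarize()].
#' @param erosion_iterations see [erode_mask()]; 0 disables erosion.
#' @return a `foreground_result`: list with `background` (C), `mask_raw`
#'   (binarization B), `mask` (after erosion), `foreground` (`I * mask`).
#' @export
segment_foreground <- function(I, template_size = c(21, 21, 5), passes = 3,
                               thre_binarization = 0.3,
                               erosion_iterations = 1, support = NULL) {
  tube <- NULL
  if (inherits(I, "sub_block")) {
    tube <- I$tube_mask
    support <- if (is.null(support)) tube else support
    I <- I$volume
  }
  C <- estimate_background(I, template_size, passes, support = support)
  B <- binarize(I, C, thre_binarization)
  Be <- if (erosion_iterations > 0) erode_mask(B, erosion_iterations) else B
  if (!is.null(tube)) Be <- Be & tube
  F <- I * Be
  structure(list(background = C, mask_raw = B, mask = Be, foreground = F),
            class = "foreground_result")
}
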