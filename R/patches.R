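#' Extract a classification patch around a candidate center
#'
#' Crops a `60 x 60 x 7`-voxel volume around the candidate's voxel (regions
#' outside the volume are zero-filled), collapses it by maximum projection
#' along z (the axial resolution of the target datasets is insufficient to
#' resolve boutons in depth), up-samples the projection bilinearly by the
#' given factor (default 4x: `240 x 240` pixels at 0.05 um for a 0.2 um
#' lateral pitch), and rescales intensities per patch to `[0, 1]` by min-max
#' normalization.
#'
#' @param volume a [bouton_volume()].
#' @param center_um candidate center, micrometres (length-3).
#' @param crop_size crop in voxels, default `c(60, 60, 7)`.
#' @param upsample integer up-sampling factor, default 4.
#' @param normalize min-max normalize the patch (default `TRUE`).
#' @return a `patch_sample`: list with `image` (2D matrix, e.g. 240 x 240),
#'   `pixel_pitch_um`, `source_center` (um), `label` (`NA` until assigned).
#' @export
extract_patch <- function(volume, center_um, crop_size = c(60, 60, 7),
                          upsample = 4, normalize = TRUE) {
  stopifnot(inherits(volume, "bouton_volume"))
  d <- dim(volume$data)
  cv <- as.integer(um_to_voxel(center_um, volume$voxel_pitch))
  if (any(cv < 1L) || any(cv > d)) {
    stop("candidate center lies outside the volume")
  }
  proj <- crop_maxproj(volume$data, cv, crop_size)
  up <- upsample_bilinear(proj, upsample)
  if (normalize) up <- minmax01(up)
  structure(list(image = up,
                 pixel_pitch_um = volume$voxel_pitch[1] / upsample,
                 source_center = as.numeric(center_um), label = NA_character_),
            class = "patch_sample")
}

# Crop a (cx, cy, cz)-centered box (zero-padded at the borders) and
# max-project it along z. For even crop sizes the center voxel sits at
# floor((size - 1) / 2) + 1 of the crop.
crop_maxproj <- function(arr, cv, crop_size) {
  d <- dim(arr)
  lo_half <- (crop_size - 1L) %/% 2L
  lo <- cv - lo_half
  hi <- lo + crop_size - 1L
  out <- array(0, crop_size)
  slo <- pmax(lo, 1L); shi <- pmin(hi, d)
  if (all(slo <= shi)) {
    out[(slo[1] - lo[1] + 1L):(shi[1] - lo[1] + 1L),
        (slo[2] - lo[2] + 1L):(shi[2] - lo[2] + 1L),
        (slo[3] - lo[3] + 1L):(shi[3] - lo[3] + 1L)] <-
      arr[slo[1]:shi[1], slo[2]:shi[2], slo[3]:shi[3], drop = FALSE]
  }
  Reduce(pmax, lapply(seq_len(crop_size[3]), function(k) out[, , k]))
}

upsample_bilinear <- function(img, factor) {
  if (factor == 1) return(img)
  EBImage::resize(img, w = nrow(img) * factor, h = ncol(img) * factor,
                  filter = "bilinear")
}

minmax01 <- function(x) {
  r <- range(x)
  if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else x * 0
}

#' Augment labeled patch samples
#'
#' Expands a set of labeled patches with the five label-preserving
#' augmentation families used for training: rotation by 90/180/270 degrees;
#' additive Gaussian, salt-and-pepper, or Poisson noise; single-pixel
#' diagonal shifts (`[1, 1]`, `[1, -1]`, `[-1, 1]`, `[-1, -1]`); scaling by
#' 1.2 or 0.82 (center-cropped or zero-padded back to size); and gray-level
#' multiplication by a random coefficient in `[0.7, 1.3]`. Deterministic
#' under a fixed seed.
#'
#' @param samples list of `patch_sample` objects (labels set).
#' @param families character subset of
#'   `c("rotation", "noise", "shift", "scale", "gray")`.
#' @param seed RNG seed for the stochastic families.
#' @return list of new `patch_sample`s (the originals are not included).
#' @export
augment_samples <- function(samples,
                            families = c("rotation", "noise", "shift",
                                         "scale", "gray"),
                            seed = 0L) {
  families <- match.arg(families, several.ok = TRUE)
  withr::with_seed(seed, {
    out <- list()
    for (s in samples) {
      imgs <- list()
      if ("rotation" %in% families) {
        imgs <- c(imgs, lapply(1:3, function(k) rot90(s$image, k)))
      }
      if ("noise" %in% families) {
        imgs <- c(imgs, list(noise_gaussian(s$image), noise_saltpepper(s$image),
                             noise_poisson(s$image)))
      }
      if ("shift" %in% families) {
        imgs <- c(imgs, lapply(list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)),
                               function(d) shift_xy(s$image, d[1], d[2])))
      }
      if ("scale" %in% families) {
        imgs <- c(imgs, list(scale_to(s$image, 1.2), scale_to(s$image, 0.82)))
      }
      if ("gray" %in% families) {
        imgs <- c(imgs, list(s$image * stats::runif(1, 0.7, 1.3)))
      }
      out <- c(out, lapply(imgs, function(im) {
        r <- s; r$image <- im; r
      }))
    }
    out
  })
}

#' Rotate a matrix by multiples of 90 degrees
#' @param m matrix; @param k number of counter-clockwise quarter turns.
#' @return rotated matrix.
#' @keywords internal
rot90 <- function(m, k = 1) {
  k <- k %% 4
  for (i in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}

noise_gaussian <- function(img, sd = 0.03) img + stats::rnorm(length(img), 0, sd)

noise_saltpepper <- function(img, frac = 0.02) {
  n <- length(img)
  k <- max(1L, round(frac * n))
  i <- sample.int(n, k)
  img[i] <- stats::rbinom(k, 1, 0.5)
  img
}

noise_poisson <- function(img, scale = 255) {
  stats::rpois(length(img), pmax(img, 0) * scale) / scale +
    array(0, dim(img))   # keep dims
}

shift_xy <- function(img, dx, dy) {
  out <- img * 0
  n1 <- nrow(img); n2 <- ncol(img)
  sx <- max(1, 1 + dx):min(n1, n1 + dx)
  sy <- max(1, 1 + dy):min(n2, n2 + dy)
  out[sx, sy] <- img[sx - dx, sy - dy]
  out
}

scale_to <- function(img, factor) {
  n1 <- nrow(img); n2 <- ncol(img)
  r <- EBImage::resize(img, w = round(n1 * factor), h = round(n2 * factor),
                       filter = "bilinear")
  out <- img * 0
  if (factor >= 1) {
    o1 <- (nrow(r) - n1) %/% 2; o2 <- (ncol(r) - n2) %/% 2
    out[] <- r[o1 + seq_len(n1), o2 + seq_len(n2)]
  } else {
    o1 <- (n1 - nrow(r)) %/% 2; o2 <- (n2 - ncol(r)) %/% 2
    out[o1 + seq_len(nrow(r)), o2 + seq_len(ncol(r))] <- r
  }
  out
}

#' Random per-batch patch augmentation for training
#'
#' Applies, independently to every image of a training mini-batch, a random
#' quarter-turn rotation, a gray-level multiplication (uniform in
#' `[0.7, 1.3]`), a one-pixel diagonal shift (with probability 1/2), and
#' additive Gaussian noise scaled to the image range. Draws from the ambient
#' RNG stream, so training remains reproducible under a fixed seed. Intended
#' as the `train_transform` argument of [train_classifier()].
#'
#' @param stack image stack `(H, W, n)` (raw intensity scale).
#' @param noise_sd Gaussian noise level as a fraction of each image's range.
#' @return transformed stack, same shape.
#' @export
random_patch_transform <- function(stack, noise_sd = 0.02) {
  n <- dim(stack)[3]
  for (i in seq_len(n)) {
    img <- stack[, , i]
    k <- sample.int(4L, 1L) - 1L
    if (k > 0) img <- rot90(img, k)
    img <- img * stats::runif(1, 0.7, 1.3)
    if (stats::runif(1) < 0.5) {
      d <- sample(c(-1L, 1L), 2L, replace = TRUE)
      img <- shift_xy(img, d[1], d[2])
    }
    rng <- diff(range(img))
    if (rng > 0) img <- img + stats::rnorm(length(img), 0, noise_sd * rng)
    stack[, , i] <- img
  }
  stack
}
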