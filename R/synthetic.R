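#' Specification of a synthetic axon scene
#'
#' Describes a simulated fluorescence sub-volume containing sparse bright
#' axons (~0.5 um diameter) on a dark background, with planted boutons
#' (local swellings with at least 2-fold the neighboring axonal width) and
#' planted non-bouton swellings (sub-threshold width inhomogeneities that
#' mimic boutons), anisotropic optical blur, a background offset and mixed
#' Gaussian + Poisson noise. The 2-fold width criterion partitions the two
#' swelling classes, mirroring how putative boutons are annotated in real
#' data.
#'
#' @param dims volume size in voxels (x, y, z).
#' @param voxel_pitch micrometres per voxel, default `c(0.2, 0.2, 1)`.
#' @param n_axons number of traced axons rendered (and present in the SWC).
#' @param axon_length_um centerline length per axon, micrometres.
#' @param axon_radius_um axon radius (default 0.25 um, i.e. ~0.5 um
#'   diameter).
#' @param axon_intensity peak centerline intensity of a plain axon
#'   (arbitrary counts).
#' @param intensity_jitter per-axon multiplicative intensity range (uniform).
#' @param bouton_density boutons per 100 um of axon.
#' @param bouton_ratio_range width-ratio range of planted boutons
#'   (all >= 2).
#' @param non_bouton_ratio_range width-ratio range of planted non-bouton
#'   swellings (all < 2).
#' @param non_bouton_per_bouton planted non-bouton swellings per bouton
#'   (default 1: a 1:1 mix).
#' @param min_spacing_um minimum arclength gap between swellings.
#' @param bump_fwhm_um arclength FWHM of the radius bump at a swelling.
#' @param intensity_exponent local brightness scales with
#'   `width_ratio ^ intensity_exponent`; the default 2 makes brightness
#'   proportional to the local cross-sectional area, so boutons are brighter
#'   as well as wider, as in real sparsely labeled axons.
#' @param blur_um anisotropic Gaussian blur sd per axis, micrometres.
#' @param background additive background offset (counts).
#' @param gaussian_sd additive Gaussian read-noise sd (counts).
#' @param poisson apply Poisson (shot) noise to the signal.
#' @param margin_um swellings are planted at least this far from the volume
#'   faces and the axon ends.
#' @param turn_sd curvature of the axon random walk (direction perturbation
#'   sd per 1 um step).
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(dims = c(300L, 300L, 40L),
                       voxel_pitch = c(0.2, 0.2, 1), n_axons = 1L,
                       axon_length_um = 200, axon_radius_um = 0.25,
                       axon_intensity = 800,
                       intensity_jitter = c(0.7, 1.3),
                       bouton_density = 5,
                       bouton_ratio_range = c(2.0, 3.5),
                       non_bouton_ratio_range = c(1.2, 1.7),
                       non_bouton_per_bouton = 1,
                       min_spacing_um = 2, bump_fwhm_um = 1,
                       intensity_exponent = 2,
                       blur_um = c(0.15, 0.15, 0.5), background = 100,
                       gaussian_sd = 5, poisson = TRUE, margin_um = 3,
                       turn_sd = 0.15) {
  spec <- as.list(environment())
  if (any(spec$bouton_ratio_range < 2)) {
    stop("bouton width ratios must be >= 2 (the annotation criterion)")
  }
  if (any(spec$non_bouton_ratio_range >= 2)) {
    stop("non-bouton width ratios must be < 2 (the annotation criterion)")
  }
  if (spec$bouton_density < 0 || spec$non_bouton_per_bouton < 0) {
    stop("densities must be >= 0")
  }
  total_density <- spec$bouton_density * (1 + spec$non_bouton_per_bouton) / 100
  if (total_density > 0 && 1 / total_density <= spec$min_spacing_um) {
    stop("swelling density incompatible with the minimum spacing of ",
         spec$min_spacing_um, " um")
  }
  class(spec) <- "scene_spec"
  spec
}

#' Benchmark scene presets
#'
#' `"pyramidal"` emulates sub-blocks of a long-range pyramidal projection
#' neuron: sparse axon, boutons of diverse width ratios (2-3.5x) and
#' intensities, non-bouton swellings planted 1:1. `"basket"` emulates a
#' local interneuron: strong, large (2.5-3.5x), densely spaced boutons on a
#' brighter axon.
#'
#' @param kind `"pyramidal"` or `"basket"`.
#' @param ... overrides passed to [scene_spec()].
#' @return a `scene_spec`.
#' @export
scene_preset <- function(kind = c("pyramidal", "basket"), ...) {
  kind <- match.arg(kind)
  args <- switch(kind,
    pyramidal = list(),
    basket = list(axon_intensity = 1200, bouton_density = 12,
                  bouton_ratio_range = c(2.5, 3.5), min_spacing_um = 2))
  do.call(scene_spec, utils::modifyList(args, list(...)))
}

#' Simulate axon centerlines and swelling annotations
#'
#' Axon centerlines are bounded-curvature random walks (1 um steps, direction
#' perturbed by `turn_sd`, reflected at the volume faces). Swellings are
#' placed along arclength by a renewal point process with a hard minimum
#' spacing; each swelling is assigned a width ratio sampled from the bouton
#' or non-bouton range (the 2-fold criterion decides the class label).
#' Swellings falling within `margin_um` of a volume face or axon end are
#' rejected.
#'
#' @param spec a [scene_spec()].
#' @param seed RNG seed; identical seeds give identical trees.
#' @return list with `axons` (each: `points` n x 3 um at 1 um steps),
#'   `swellings` (data frame: `axon`, `s`, `x_um`, `y_um`, `z_um`, `class`,
#'   `width_ratio`), and `skeleton` (a `neuron_skeleton`).
#' @export
simulate_axon_tree <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "scene_spec"))
  extent <- (spec$dims - 1) * spec$voxel_pitch
  p_bouton <- 1 / (1 + spec$non_bouton_per_bouton)
  total_density <- spec$bouton_density * (1 + spec$non_bouton_per_bouton) / 100
  mean_gap <- if (total_density > 0) 1 / total_density else Inf
  withr::with_seed(seed, {
    axons <- list()
    sw <- NULL
    for (a in seq_len(spec$n_axons)) {
      pts <- walk_centerline(spec, extent)
      axons[[a]] <- list(points = pts)
      if (total_density == 0) next
      total_s <- nrow(pts) - 1      # 1 um steps
      rate <- 1 / (mean_gap - spec$min_spacing_um)
      s <- stats::rexp(1, total_density)   # first arrival
      while (s < total_s) {
        ratio_is_bouton <- stats::runif(1) < p_bouton
        ratio <- if (ratio_is_bouton) {
          stats::runif(1, spec$bouton_ratio_range[1],
                       spec$bouton_ratio_range[2])
        } else {
          stats::runif(1, spec$non_bouton_ratio_range[1],
                       spec$non_bouton_ratio_range[2])
        }
        pos <- interp_arclength(pts, s)
        ok <- s > spec$margin_um && s < total_s - spec$margin_um &&
          all(pos >= spec$margin_um) && all(pos <= extent - spec$margin_um)
        if (ok) {
          sw <- rbind(sw, data.frame(
            axon = a, s = s, x_um = pos[1], y_um = pos[2], z_um = pos[3],
            class = if (ratio_is_bouton) "bouton" else "non_bouton",
            width_ratio = ratio))
        }
        s <- s + spec$min_spacing_um + stats::rexp(1, rate)
      }
    }
    if (is.null(sw)) {
      sw <- data.frame(axon = integer(0), s = numeric(0), x_um = numeric(0),
                       y_um = numeric(0), z_um = numeric(0),
                       class = character(0), width_ratio = numeric(0))
    }
    list(axons = axons, swellings = sw,
         skeleton = tree_to_skeleton(axons, spec$axon_radius_um))
  })
}

walk_centerline <- function(spec, extent) {
  lo <- pmin(extent * 0.45, 6)   # start away from the faces
  start <- stats::runif(3, lo, extent - lo)
  theta <- stats::runif(1, 0, 2 * pi)
  dir <- c(cos(theta), sin(theta), stats::rnorm(1, 0, 0.1))
  dir <- dir / sqrt(sum(dir^2))
  n <- ceiling(spec$axon_length_um) + 1
  pts <- matrix(0, n, 3)
  pts[1, ] <- start
  margin <- 1
  for (i in 2:n) {
    dir <- dir + stats::rnorm(3, 0, spec$turn_sd) * c(1, 1, 0.25)
    dir <- dir / sqrt(sum(dir^2))
    nxt <- pts[i - 1, ] + dir
    for (ax in 1:3) {
      if (nxt[ax] < margin || nxt[ax] > extent[ax] - margin) {
        dir[ax] <- -dir[ax]
        nxt[ax] <- pts[i - 1, ax] + dir[ax]
      }
    }
    pts[i, ] <- pmin(pmax(nxt, margin), extent - margin)
  }
  pts
}

interp_arclength <- function(pts, s) {
  # pts are at ~1 um steps; interpolate position at arclength s
  seg <- sqrt(rowSums(diff(pts)^2))
  cs <- c(0, cumsum(seg))
  i <- findInterval(s, cs, all.inside = TRUE)
  t <- (s - cs[i]) / max(seg[i], 1e-12)
  pts[i, ] + t * (pts[i + 1, ] - pts[i, ])
}

tree_to_skeleton <- function(axons, radius) {
  if (length(axons) == 0L) {
    empty <- data.frame(id = integer(0), type = integer(0), x = numeric(0),
                        y = numeric(0), z = numeric(0), radius = numeric(0),
                        parent = integer(0))
    class(empty) <- c("neuron_skeleton", "data.frame")
    return(empty)
  }
  rows <- NULL
  next_id <- 1L
  for (a in seq_along(axons)) {
    pts <- axons[[a]]$points
    n <- nrow(pts)
    ids <- seq.int(next_id, next_id + n - 1L)
    rows <- rbind(rows, data.frame(
      id = ids, type = 2L, x = pts[, 1], y = pts[, 2], z = pts[, 3],
      radius = radius, parent = c(-1L, ids[-n])))
    next_id <- next_id + n
  }
  validate_skeleton(rows, "synthetic tree")
}

#' Simulate a complete synthetic scene
#'
#' Renders each axon as a Gaussian cross-section tube whose local radius is
#' the base radius times a smooth width-ratio profile (a Gaussian arclength
#' bump at each swelling), with local brightness scaling with the width
#' ratio so boutons are brighter as well as wider; applies anisotropic
#' Gaussian blur; and adds the background offset, Poisson shot noise and
#' Gaussian read noise. Fully deterministic given `spec` and `seed`.
#'
#' @param spec a [scene_spec()].
#' @param seed RNG seed.
#' @param output_dir if non-`NULL`, write `volume.tif` (16-bit multi-page
#'   TIFF), `skeleton.swc`, `truth.csv` and `spec.yaml` there.
#' @return a `synthetic_scene`: list with `volume` ([bouton_volume()]),
#'   `skeleton`, `truth` (data frame: `x_um`, `y_um`, `z_um`, `class`,
#'   `width_ratio`), `spec`, `seed`.
#' @export
simulate_scene <- function(spec, seed = 1L, output_dir = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  tree <- simulate_axon_tree(spec, seed)
  arr <- array(0, spec$dims)
  withr::with_seed(seed + 1000000L, {
    gains <- stats::runif(length(tree$axons), spec$intensity_jitter[1],
                          spec$intensity_jitter[2])
    for (a in seq_along(tree$axons)) {
      arr <- render_axon(arr, tree$axons[[a]]$points,
                         tree$swellings[tree$swellings$axon == a, ,
                                        drop = FALSE],
                         spec, spec$axon_intensity * gains[a])
    }
    if (any(spec$blur_um > 0)) arr <- gaussian_blur(arr, spec$blur_um,
                                                    spec$voxel_pitch)
    if (spec$poisson) {
      arr[] <- stats::rpois(length(arr), pmax(arr, 0))
    }
    arr <- arr + spec$background
    if (spec$gaussian_sd > 0) {
      arr <- arr + stats::rnorm(length(arr), 0, spec$gaussian_sd)
    }
    arr[arr < 0] <- 0
  })
  truth <- tree$swellings[, c("x_um", "y_um", "z_um", "class", "width_ratio")]
  rownames(truth) <- NULL
  scene <- structure(list(volume = bouton_volume(arr, spec$voxel_pitch),
                          skeleton = tree$skeleton, truth = truth,
                          spec = spec, seed = seed),
                     class = "synthetic_scene")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_volume_tiff(scene$volume, file.path(output_dir, "volume.tif"))
    write_swc(scene$skeleton, file.path(output_dir, "skeleton.swc"))
    utils::write.csv(truth, file.path(output_dir, "truth.csv"),
                     row.names = FALSE)
    yaml::write_yaml(c(unclass(spec), list(seed = seed)),
                     file.path(output_dir, "spec.yaml"))
  }
  scene
}

# Width-ratio profile along arclength: 1 plus a Gaussian bump per swelling.
width_profile <- function(s, swellings, bump_sd) {
  ratio <- rep(1, length(s))
  for (k in seq_len(nrow(swellings))) {
    ratio <- ratio + (swellings$width_ratio[k] - 1) *
      exp(-(s - swellings$s[k])^2 / (2 * bump_sd^2))
  }
  ratio
}

render_axon <- function(arr, pts, swellings, spec, intensity) {
  ds <- 0.1
  fine <- resample_polyline(pts, ds)
  seg <- sqrt(rowSums(diff(fine)^2))
  s <- c(0, cumsum(seg))
  bump_sd <- spec$bump_fwhm_um / (2 * sqrt(2 * log(2)))
  ratio <- width_profile(s, swellings, bump_sd)
  r <- spec$axon_radius_um * ratio
  amp <- intensity * ratio^spec$intensity_exponent
  add_blobs(arr, fine, r, amp, spec$voxel_pitch)
}

# Composite isotropic Gaussian blobs (sd in um) into a voxel array by
# maximum blending: a voxel takes the brightest profile among nearby
# centerline samples. Unlike summation, this renders tubes of uniform
# brightness regardless of curvature or sample spacing, so the only local
# intensity structure along an axon is the planted swelling profile.
add_blobs <- function(arr, centers_um, sd_um, amp, pitch) {
  d <- dim(arr)
  for (i in seq_len(nrow(centers_um))) {
    cv <- centers_um[i, ] / pitch          # continuous 0-based voxel coords
    half <- ceiling(3 * sd_um[i] / pitch)
    lo <- pmax(floor(cv - half), 0)
    hi <- pmin(ceiling(cv + half), d - 1)
    if (any(lo > hi)) next
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    gx <- exp(-((xs - cv[1]) * pitch[1])^2 / (2 * sd_um[i]^2))
    gy <- exp(-((ys - cv[2]) * pitch[2])^2 / (2 * sd_um[i]^2))
    gz <- exp(-((zs - cv[3]) * pitch[3])^2 / (2 * sd_um[i]^2))
    blob <- amp[i] * outer(outer(gx, gy), gz)
    arr[xs + 1, ys + 1, zs + 1] <-
      pmax(arr[xs + 1, ys + 1, zs + 1, drop = FALSE], blob)
  }
  arr
}

# Separable anisotropic Gaussian blur (sd per axis in um).
gaussian_blur <- function(arr, sd_um, pitch) {
  for (ax in 1:3) {
    sd_vox <- sd_um[ax] / pitch[ax]
    if (sd_vox <= 0) next
    h <- max(1L, ceiling(3 * sd_vox))
    k <- stats::dnorm(-h:h, sd = sd_vox)
    arr <- filter_axis(arr, k / sum(k), ax)
  }
  arr
}

#' Generate labeled training patches from simulated swellings
#'
#' Renders, for each sample, a small volume containing one axon crossing the
#' center (random orientation and brightness, the scene's blur/noise model)
#' with, at the center, either a planted bouton (positive class), or --- for
#' the negative class --- a sub-threshold non-bouton swelling or a plain
#' axon, and optionally a distractor fiber passing nearby. Additional
#' swellings of either class are planted along the axon away from the
#' center (and on the distractor), so the classifier learns that the label
#' is carried by the structure at the patch center, not by bright neighbors
#' --- the situation that arises around densely spaced boutons. Returns the raw
#' (unnormalized) 60 x 60 maximum projections; [training_patch_preprocess()]
#' up-samples and normalizes them to the network input exactly as
#' [extract_patch()] does.
#'
#' @param n number of patches; class balance is `positive_fraction` within
#'   one sample.
#' @param seed RNG seed.
#' @param spec a [scene_spec()] supplying radii, ratio ranges, blur and
#'   noise parameters.
#' @param positive_fraction fraction of bouton patches (default 0.5, as in
#'   a balanced manually labeled training set).
#' @param plain_negative_fraction fraction of the negative class rendered
#'   as plain axon (no swelling) rather than a non-bouton swelling.
#' @param distractor_prob probability of an extra fiber crossing the patch.
#' @param neighbor_rate expected number of additional off-center swellings
#'   per patch (Poisson), planted at least the scene's minimum spacing from
#'   the center.
#' @return list with `images` (array `60 x 60 x n` of raw projections),
#'   `labels` (character), `meta` (data frame with `width_ratio`,
#'   `intensity`).
#' @export
generate_training_patches <- function(n = 5000L, seed = 0L,
                                      spec = scene_spec(),
                                      positive_fraction = 0.5,
                                      plain_negative_fraction = 0.5,
                                      distractor_prob = 0.3,
                                      neighbor_rate = 1.2) {
  n_pos <- round(n * positive_fraction)
  labels <- rep(c("bouton", "non_bouton"), c(n_pos, n - n_pos))
  dims <- c(66L, 66L, 9L)
  pitch <- spec$voxel_pitch
  center_um <- (dims %/% 2L) * pitch   # 0-based center voxel position
  imgs <- array(0, c(60, 60, n))
  meta <- data.frame(width_ratio = numeric(n), intensity = numeric(n))
  withr::with_seed(seed, {
    for (i in seq_len(n)) {
      positive <- labels[i] == "bouton"
      ratio <- if (positive) {
        stats::runif(1, spec$bouton_ratio_range[1], spec$bouton_ratio_range[2])
      } else if (stats::runif(1) < plain_negative_fraction) {
        1
      } else {
        stats::runif(1, spec$non_bouton_ratio_range[1],
                     spec$non_bouton_ratio_range[2])
      }
      I0 <- spec$axon_intensity *
        stats::runif(1, spec$intensity_jitter[1], spec$intensity_jitter[2])
      arr <- render_patch_volume(dims, pitch, center_um, ratio, I0, spec,
                                 distractor = stats::runif(1) < distractor_prob,
                                 neighbor_rate = neighbor_rate)
      vol <- bouton_volume(arr, pitch)
      imgs[, , i] <- crop_maxproj(vol$data,
                                  as.integer(um_to_voxel(center_um, pitch)),
                                  c(60L, 60L, 7L))
      meta$width_ratio[i] <- ratio
      meta$intensity[i] <- I0
    }
  })
  list(images = imgs, labels = labels, meta = meta)
}

# Render one small patch volume: an axon through `center_um` with a central
# swelling of the given width ratio (1 = plain axon), plus optional
# off-center neighbor swellings and a distractor fiber. Uses the ambient
# RNG.
render_patch_volume <- function(dims, pitch, center_um, ratio, intensity,
                                spec, distractor = FALSE,
                                neighbor_rate = 0) {
  extent <- (dims - 1) * pitch
  half_len <- sqrt(sum(extent[1:2]^2)) / 2 + 1
  theta <- stats::runif(1, 0, 2 * pi)
  # axial tilt matches the scene walks, which range from in-plane to
  # steeply diving stretches (the latter produce plane-crossing bright
  # spots the classifier must learn to reject)
  dirv <- c(cos(theta), sin(theta), stats::rnorm(1, 0, 0.25))
  dirv <- dirv / sqrt(sum(dirv^2))
  ts <- seq(-half_len, half_len, by = 1)
  pts <- sweep(outer(ts, dirv), 2, center_um, `+`)
  sw <- data.frame(axon = integer(0), s = numeric(0), x_um = numeric(0),
                   y_um = numeric(0), z_um = numeric(0), class = character(0),
                   width_ratio = numeric(0))
  if (ratio > 1) {
    sw <- rbind(sw, data.frame(axon = 1L, s = half_len, x_um = center_um[1],
                               y_um = center_um[2], z_um = center_um[3],
                               class = "x", width_ratio = ratio))
  }
  sample_ratio <- function() {
    if (stats::runif(1) < 0.5) {
      stats::runif(1, spec$bouton_ratio_range[1], spec$bouton_ratio_range[2])
    } else {
      stats::runif(1, spec$non_bouton_ratio_range[1],
                   spec$non_bouton_ratio_range[2])
    }
  }
  n_nb <- stats::rpois(1, neighbor_rate)
  for (k in seq_len(n_nb)) {
    s_nb <- half_len +
      sample(c(-1, 1), 1) * stats::runif(1, spec$min_spacing_um, half_len)
    sw <- rbind(sw, data.frame(axon = 1L, s = s_nb, x_um = NA_real_,
                               y_um = NA_real_, z_um = NA_real_, class = "x",
                               width_ratio = sample_ratio()))
  }
  arr <- array(0, dims)
  arr <- render_axon(arr, pts, sw, spec, intensity)
  if (distractor) {
    off <- stats::runif(2, 1.5, 3) * sample(c(-1, 1), 2, replace = TRUE)
    theta2 <- stats::runif(1, 0, 2 * pi)
    dir2 <- c(cos(theta2), sin(theta2), 0)
    pts2 <- sweep(outer(ts, dir2), 2, center_um + c(off, 0), `+`)
    sw2 <- sw[0, ]
    if (stats::runif(1) < 0.5) {
      sw2 <- data.frame(axon = 1L, s = stats::runif(1, 0, 2 * half_len),
                        x_um = NA_real_, y_um = NA_real_, z_um = NA_real_,
                        class = "x", width_ratio = sample_ratio())
    }
    arr <- render_axon(arr, pts2, sw2, spec,
                       intensity * stats::runif(1, 0.5, 1.2))
  }
  if (any(spec$blur_um > 0)) arr <- gaussian_blur(arr, spec$blur_um, pitch)
  if (spec$poisson) arr[] <- stats::rpois(length(arr), pmax(arr, 0))
  arr <- arr + spec$background
  if (spec$gaussian_sd > 0) arr <- arr + stats::rnorm(length(arr), 0,
                                                      spec$gaussian_sd)
  arr[arr < 0] <- 0
  arr
}

#' Up-sample and normalize raw training projections to the network input
#'
#' Applies the same bilinear 4x up-sampling and per-patch min-max
#' normalization as [extract_patch()] to a stack of raw 60 x 60 maximum
#' projections.
#'
#' @param stack array `60 x 60 x n`.
#' @param upsample up-sampling factor (default 4).
#' @return array `(60*upsample) x (60*upsample) x n`.
#' @export
training_patch_preprocess <- function(stack, upsample = 4) {
  n <- dim(stack)[3]
  out <- array(0, c(dim(stack)[1] * upsample, dim(stack)[2] * upsample, n))
  for (i in seq_len(n)) {
    out[, , i] <- minmax01(upsample_bilinear(stack[, , i], upsample))
  }
  out
}
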