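#' 3D fluorescence volume with voxel pitch
#'
#' A `bouton_volume` wraps a numeric 3D array of intensities together with the
#' physical voxel pitch in micrometres per axis. The array is indexed
#' `data[ix, iy, iz]`; the physical position of a voxel is its 0-based index
#' times the pitch, so voxel `(1, 1, 1)` (in R's 1-based indexing) sits at the
#' origin of the micrometre frame shared with SWC skeletons.
#'
#' @param data numeric 3D array of intensities.
#' @param voxel_pitch numeric length-3 vector, micrometres per voxel along
#'   (x, y, z). Default `c(0.2, 0.2, 1)` matches sub-micron axial-scanning
#'   fluorescence datasets of single neurons.
#' @return an object of class `bouton_volume` with elements `data` and
#'   `voxel_pitch`.
#' @export
bouton_volume <- function(data, voxel_pitch = c(0.2, 0.2, 1)) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  voxel_pitch <- as.numeric(voxel_pitch)
  if (length(voxel_pitch) != 3L || any(!is.finite(voxel_pitch)) ||
      any(voxel_pitch <= 0)) {
    stop("`voxel_pitch` must be 3 positive finite numbers (um per axis)")
  }
  structure(list(data = data, voxel_pitch = voxel_pitch),
            class = "bouton_volume")
}

#' @export
print.bouton_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bouton_volume> %d x %d x %d voxels, pitch %.3g x %.3g x %.3g um\n",
              d[1], d[2], d[3],
              x$voxel_pitch[1], x$voxel_pitch[2], x$voxel_pitch[3]))
  invisible(x)
}

#' @export
dim.bouton_volume <- function(x) dim(x$data)

#' Convert between voxel indices and micrometre coordinates
#'
#' Positions use the convention `position_um = (index - 1) * voxel_pitch`
#' (0-based voxel indices times pitch).
#'
#' @param idx matrix (n x 3) or length-3 vector of 1-based voxel indices.
#' @param voxel_pitch micrometres per voxel along (x, y, z).
#' @return matrix (n x 3) of coordinates, micrometres.
#' @export
voxel_to_um <- function(idx, voxel_pitch) {
  idx <- rbind2mat(idx)
  sweep(idx - 1, 2, voxel_pitch, `*`)
}

#' @rdname voxel_to_um
#' @param um matrix (n x 3) or length-3 vector of micrometre coordinates.
#' @return for `um_to_voxel`, the nearest 1-based voxel indices (n x 3).
#' @export
um_to_voxel <- function(um, voxel_pitch) {
  um <- rbind2mat(um)
  round(sweep(um, 2, voxel_pitch, `/`)) + 1
}

rbind2mat <- function(x) {
  if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
}

#' Read a multi-page TIFF stack as a volume
#'
#' Pages are treated as z-planes with rows = y and columns = x. Intensities
#' stored as 8/16-bit integers are rescaled back to their integer range
#' (the `tiff` package reads them into `[0, 1]`).
#'
#' @param path path to a multi-page TIFF file.
#' @param voxel_pitch micrometres per voxel (x, y, z).
#' @return a [bouton_volume()].
#' @export
read_volume_tiff <- function(path, voxel_pitch = c(0.2, 0.2, 1)) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bits <- attr(pages[[1]], "bits.per.sample")
  scale <- if (!is.null(bits) && bits %in% c(8L, 16L)) 2^bits - 1 else 1
  arr <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]]) * scale
  bouton_volume(arr, voxel_pitch)
}

#' Write a volume as a 16-bit multi-page TIFF
#'
#' Intensities are rounded to integers and clipped to `[0, 65535]`.
#'
#' @param volume a [bouton_volume()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(volume, path) {
  stopifnot(inherits(volume, "bouton_volume"))
  d <- dim(volume$data)
  pages <- lapply(seq_len(d[3]), function(k) {
    m <- t(volume$data[, , k])
    m <- round(pmin(pmax(m, 0), 65535))
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}
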