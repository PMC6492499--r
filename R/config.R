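#' Default pipeline configuration
#'
#' Every parameter of the pipeline has a default here, so a minimal config
#' (possibly just file paths) is runnable. A YAML file with any subset of
#' these sections can be merged over the defaults with [load_config()].
#'
#' Sections:
#' \describe{
#'   \item{volume}{`voxel_pitch` (um per axis, x/y/z).}
#'   \item{skeleton}{`segment_length`, `overlap` (um) for redundant tree
#'     division; `axon_only` (restrict to SWC structure code 2);
#'     `swc_unit_scale` (factor converting SWC units to um); `tube_radii`
#'     (voxels per axis), `tube_shape` (`"ellipsoid"` or `"box"`);
#'     `merge_radius` (um) for deduplicating candidates across segments.}
#'   \item{foreground}{`template_size` (voxels), `passes`,
#'     `thre_binarization`, `erosion_iterations`.}
#'   \item{detector}{`sigma` (um, about one third of the average bouton
#'     radius), `thre_search`, `R_min` (um), `min_rho_frac`,
#'     `kde_bandwidth` (per-axis), `kde_grid`, `normalization`.}
#'   \item{classifier}{`prob_threshold` for keeping a candidate; `crop_size`
#'     (voxels), `upsample` factor for patch preparation; `model` path.}
#'   \item{evaluation}{`tolerance` (um) for one-to-one matching.}
#'   \item{pipeline}{`ablation` (skip the classifier stage), `seed`.}
#' }
#'
#' @return nested named list of parameters.
#' @export
default_config <- function() {
  list(
    volume = list(voxel_pitch = c(0.2, 0.2, 1.0)),
    skeleton = list(segment_length = 100, overlap = 10, axon_only = FALSE,
                    swc_unit_scale = 1, tube_radii = c(8, 8, 4),
                    tube_shape = "ellipsoid", merge_radius = 1.2),
    foreground = list(template_size = c(21, 21, 5), passes = 3,
                      thre_binarization = 0.3, erosion_iterations = 1),
    detector = list(sigma = 0.17, thre_search = 0.2, R_min = 0.4,
                    min_rho_frac = 0.08,
                    kde_bandwidth = c(0.01, 0.02), kde_grid = 256L,
                    normalization = "window"),
    classifier = list(prob_threshold = 0.5, crop_size = c(60, 60, 7),
                      upsample = 4, model = NULL),
    evaluation = list(tolerance = 1.2),
    pipeline = list(ablation = FALSE, seed = 1L)
  )
}

#' Load a YAML configuration merged over the defaults
#'
#' @param path path to a YAML file (may specify any subset of parameters),
#'   or `NULL` for pure defaults.
#' @return nested list as in [default_config()].
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- modifyList(cfg, user)
  }
  cfg
}
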