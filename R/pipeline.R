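#' Run the full bouton-detection pipeline
#'
#' Orchestrates the whole flow: divide the traced arbor into redundant
#' segments, extract the tubular sub-volume of each segment, segment the
#' foreground and detect candidate swelling centers by density-peak
#' clustering per sub-block, merge the per-segment candidates, and (unless
#' the ablation flag is set) filter non-bouton swellings with the patch
#' classifier. When ground truth is supplied, detections are evaluated with
#' one-to-one matching at the configured tolerance.
#'
#' @param config nested parameter list (see [default_config()]), or a path
#'   to a YAML config. Paths in `config$paths` (`volume`, `swc`, `model`,
#'   `truth`, `output_dir`) are used for any input not passed directly.
#' @param volume a [bouton_volume()] (overrides `config$paths$volume`).
#' @param skeleton a `neuron_skeleton` (overrides `config$paths$swc`).
#' @param truth optional ground-truth data frame with `x_um`, `y_um`,
#'   `z_um` and (optionally) `class`; only rows with `class == "bouton"`
#'   (or all rows if there is no `class` column) are treated as true
#'   boutons.
#' @param classifier a `trained_classifier` (overrides
#'   `config$paths$model`); required unless `config$pipeline$ablation` is
#'   `TRUE`.
#' @param output_dir if non-`NULL`, write `detections.csv`, `report.json`
#'   (when truth is given), `config.yaml` (the resolved configuration) and
#'   `run.log` there.
#' @param verbose log progress to stderr.
#' @return a `pipeline_result`: list with `candidates` (merged initial
#'   detection), `detections` (after filtering; equal to the candidates in
#'   an ablation run), `report` (an `evaluation_report` or `NULL`),
#'   `n_segments`, `log` (character vector).
#' @export
run_pipeline <- function(config = default_config(), volume = NULL,
                         skeleton = NULL, truth = NULL, classifier = NULL,
                         output_dir = NULL, verbose = FALSE) {
  if (is.character(config)) config <- load_config(config)
  config <- utils::modifyList(default_config(), config)
  paths <- config$paths %||% list()
  if (is.null(volume)) {
    if (is.null(paths$volume)) stop("no volume given: supply `volume` or ",
                                    "set config paths$volume")
    volume <- read_volume_tiff(paths$volume, config$volume$voxel_pitch)
  }
  if (is.null(skeleton)) {
    if (is.null(paths$swc)) stop("no skeleton given: supply `skeleton` or ",
                                 "set config paths$swc")
    skeleton <- read_swc(paths$swc,
                         unit_scale = config$skeleton$swc_unit_scale %||% 1)
  }
  ablation <- isTRUE(config$pipeline$ablation)
  if (!ablation && is.null(classifier)) {
    if (is.null(config$classifier$model) && is.null(paths$model)) {
      stop("no classifier model: supply `classifier`, set paths$model, or ",
           "enable the ablation flag")
    }
    classifier <- load_classifier(paths$model %||% config$classifier$model)
  }
  if (is.null(truth) && !is.null(paths$truth)) {
    truth <- utils::read.csv(paths$truth)
  }
  logs <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    logs <<- c(logs, line)
    if (verbose) message(line)
  }
  segs <- divide_tree(skeleton, segment_length = config$skeleton$segment_length,
                      overlap = config$skeleton$overlap,
                      axon_only = isTRUE(config$skeleton$axon_only))
  note("divided skeleton into %d segments (length %g um, overlap %g um)",
       length(segs), config$skeleton$segment_length, config$skeleton$overlap)
  per_seg <- lapply(segs, function(seg) {
    block <- extract_tube(volume, seg, tube_radii = config$skeleton$tube_radii,
                          shape = config$skeleton$tube_shape)
    cand <- detect_block(block, config[c("foreground", "detector")])
    note("segment %d: %d candidates", attr(seg, "segment_index"), nrow(cand))
    cand
  })
  candidates <- merge_candidates(per_seg,
                                 merge_radius = config$skeleton$merge_radius)
  note("merged candidates: %d", nrow(candidates))
  detections <- if (ablation) {
    note("ablation run: classifier stage skipped")
    cbind(candidates, prob = rep(NA_real_, nrow(candidates)))
  } else {
    det <- filter_candidates(candidates, classifier, volume,
                             prob_threshold = config$classifier$prob_threshold,
                             crop_size = config$classifier$crop_size,
                             upsample = config$classifier$upsample)
    note("after classifier filtering (threshold %.2f): %d detections",
         config$classifier$prob_threshold, nrow(det))
    det
  }
  report <- NULL
  if (!is.null(truth)) {
    gt <- if ("class" %in% names(truth)) {
      truth[truth$class == "bouton", , drop = FALSE]
    } else truth
    report <- compute_metrics(gt, detections,
                              tolerance = config$evaluation$tolerance)
    note("evaluation: M=%d N=%d P=%d precision %.3f recall %.3f F1 %.3f",
         report$M, report$N, report$P, report$precision, report$recall,
         report$f1)
  }
  result <- structure(list(candidates = candidates, detections = detections,
                           report = report, n_segments = length(segs),
                           log = logs),
                      class = "pipeline_result")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_detections_csv(detections, file.path(output_dir, "detections.csv"))
    if (!is.null(report)) {
      write_report(report, file.path(output_dir, "report.json"),
                   file.path(output_dir, "matched_pairs.csv"))
    }
    yaml::write_yaml(config, file.path(output_dir, "config.yaml"))
    writeLines(logs, file.path(output_dir, "run.log"))
  }
  result
}

#' Write / read a detection table as CSV
#'
#' Standard column layout: `id, x_um, y_um, z_um, rho, delta, prob, label`.
#'
#' @param detections detections or candidates data frame.
#' @param path CSV file path.
#' @return `path` invisibly (write); the data frame (read).
#' @export
write_detections_csv <- function(detections, path) {
  n <- nrow(detections)
  out <- data.frame(id = seq_len(n),
                    x_um = detections$x_um, y_um = detections$y_um,
                    z_um = detections$z_um, rho = detections$rho,
                    delta = detections$delta,
                    prob = if ("prob" %in% names(detections))
                      detections$prob else rep(NA_real_, n),
                    label = rep("bouton", n))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) {
  if (!file.exists(path)) stop("detections file not found: ", path)
  utils::read.csv(path)
}
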