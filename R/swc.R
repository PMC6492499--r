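#' Read a neuron skeleton from an SWC file
#'
#' Parses the standard whitespace-delimited 7-column SWC morphology format
#' (`id type x y z radius parent`, `#` comments allowed) and validates tree
#' connectivity: node ids must be unique, every non-root `parent` must
#' reference an existing node, and coordinates must be finite.
#'
#' @param path path to an SWC file.
#' @param unit_scale multiplicative factor applied to x, y, z and radius to
#'   convert the file's units to micrometres (default 1: file already in um).
#' @return a `neuron_skeleton`: a data frame with columns `id`, `type`, `x`,
#'   `y`, `z`, `radius`, `parent` (coordinates in micrometres; roots have
#'   `parent == -1`).
#' @export
read_swc <- function(path, unit_scale = 1) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0L) stop("SWC file contains no node lines: ", path)
  fields <- strsplit(trimws(lines[rows]), "\\s+")
  bad <- which(vapply(fields, length, 1L) != 7L)
  if (length(bad)) {
    stop(sprintf("malformed SWC line %d in %s: expected 7 columns, found %d",
                 rows[bad[1]], path, length(fields[[bad[1]]])))
  }
  num <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE))
  nn <- which(apply(num, 1, function(r) any(is.na(r))))
  if (length(nn)) {
    stop(sprintf("malformed SWC line %d in %s: non-numeric field",
                 rows[nn[1]], path))
  }
  nodes <- data.frame(id = as.integer(num[, 1]), type = as.integer(num[, 2]),
                      x = num[, 3] * unit_scale, y = num[, 4] * unit_scale,
                      z = num[, 5] * unit_scale,
                      radius = num[, 6] * unit_scale,
                      parent = as.integer(num[, 7]))
  validate_skeleton(nodes, path)
}

validate_skeleton <- function(nodes, context = "skeleton") {
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node id in ", context, ": ",
         nodes$id[duplicated(nodes$id)][1])
  }
  if (any(!is.finite(as.matrix(nodes[c("x", "y", "z")])))) {
    stop("non-finite coordinate in ", context)
  }
  nonroot <- nodes$parent >= 0
  missing <- setdiff(nodes$parent[nonroot], nodes$id)
  if (length(missing)) {
    stop("dangling parent id in ", context, ": node references parent ",
         missing[1], " which does not exist")
  }
  if (!any(!nonroot)) stop("skeleton has no root node (parent -1) in ", context)
  class(nodes) <- c("neuron_skeleton", "data.frame")
  nodes
}

#' Write a neuron skeleton to an SWC file
#'
#' @param skeleton a `neuron_skeleton` (see [read_swc()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(skeleton, path) {
  lines <- sprintf("%d %d %g %g %g %g %d",
                   skeleton$id, skeleton$type, skeleton$x, skeleton$y,
                   skeleton$z, skeleton$radius, skeleton$parent)
  writeLines(c("# id type x y z radius parent", lines), path)
  invisible(path)
}
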