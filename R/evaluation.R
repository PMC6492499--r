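#' Match detections to ground truth within a distance tolerance
#'
#' Builds one-to-one matched pairs between ground-truth points and detected
#' points: all pairs within `tolerance` micrometres (inclusive) are formed
#' greedily in ascending distance order, ties broken by `(gt_id, det_id)`,
#' and each point participates in at most one pair. The greedy assignment is
#' then extended along augmenting paths to maximum cardinality, so the
#' matched-pair count equals that of an exhaustive optimal one-to-one
#' matching. One-to-one matching prevents a single detection from matching
#' several truths and inflating the matched count.
#'
#' @param ground_truth,detections matrices or data frames of point
#'   coordinates in micrometres; data frames may use columns
#'   `x_um`/`y_um`/`z_um` or `x`/`y`/`z`.
#' @param tolerance matching tolerance, micrometres (default 1.2).
#' @return data frame with columns `gt_id`, `det_id`, `distance` (one row
#'   per matched pair).
#' @export
match_detections <- function(ground_truth, detections, tolerance = 1.2) {
  stopifnot(tolerance > 0)
  G <- points_matrix(ground_truth)
  D <- points_matrix(detections)
  if (nrow(G) == 0L || nrow(D) == 0L) {
    return(data.frame(gt_id = integer(0), det_id = integer(0),
                      distance = numeric(0)))
  }
  dist2 <- outer(rowSums(G^2), rowSums(D^2), `+`) - 2 * G %*% t(D)
  dist <- sqrt(pmax(dist2, 0))
  cand <- which(dist <= tolerance + 1e-9, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    return(data.frame(gt_id = integer(0), det_id = integer(0),
                      distance = numeric(0)))
  }
  dd <- dist[cand]
  ord <- order(dd, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  dd <- dd[ord]
  used_g <- logical(nrow(G)); used_d <- logical(nrow(D))
  match_of <- integer(nrow(D))   # det -> gt assignment (0 = unmatched)
  for (i in seq_len(nrow(cand))) {
    g <- cand[i, 1]; d <- cand[i, 2]
    if (!used_g[g] && !used_d[d]) {
      used_g[g] <- TRUE; used_d[d] <- TRUE; match_of[d] <- g
    }
  }
  # extend to maximum cardinality along augmenting paths (deterministic:
  # gt in id order, detections in ascending distance order per gt)
  adj <- lapply(seq_len(nrow(G)), function(g) {
    rows <- which(cand[, 1] == g)
    cand[rows, 2]    # already in ascending distance order
  })
  aug_seen <- logical(nrow(D))
  augment <- function(g) {
    for (d in adj[[g]]) {
      if (aug_seen[d]) next
      aug_seen[d] <<- TRUE
      if (match_of[d] == 0L || augment(match_of[d])) {
        match_of[d] <<- g
        return(TRUE)
      }
    }
    FALSE
  }
  for (g in which(!used_g)) {
    if (length(adj[[g]])) {
      aug_seen[] <- FALSE
      if (augment(g)) used_g[g] <- TRUE
    }
  }
  d_idx <- which(match_of > 0L)
  g_idx <- match_of[d_idx]
  ord2 <- order(g_idx)
  data.frame(gt_id = as.integer(g_idx[ord2]),
             det_id = as.integer(d_idx[ord2]),
             distance = dist[cbind(g_idx[ord2], d_idx[ord2])])
}

points_matrix <- function(x) {
  if (is.data.frame(x)) {
    cols <- if (all(c("x_um", "y_um", "z_um") %in% names(x)))
      c("x_um", "y_um", "z_um") else c("x", "y", "z")
    x <- as.matrix(x[, cols, drop = FALSE])
  }
  x <- rbind2mat(x)
  storage.mode(x) <- "double"
  x
}

#' Precision, recall and F1 of matched detections
#'
#' With `M` ground-truth cases, `N` detections, and `P` one-to-one matched
#' pairs within the tolerance, precision is `P/N`, recall is `P/M`, and F1
#' is their harmonic mean. Empty denominators yield 0 with a warning.
#'
#' @inheritParams match_detections
#' @return an `evaluation_report`: list with `M`, `N`, `P`, `precision`,
#'   `recall`, `f1`, and the matched `pairs` data frame.
#' @export
compute_metrics <- function(ground_truth, detections, tolerance = 1.2) {
  pairs <- match_detections(ground_truth, detections, tolerance)
  M <- nrow(points_matrix(ground_truth))
  N <- nrow(points_matrix(detections))
  P <- nrow(pairs)
  if (N == 0L) warning("no detections: precision defined as 0")
  if (M == 0L) warning("no ground truth: recall defined as 0")
  precision <- if (N > 0) P / N else 0
  recall <- if (M > 0) P / M else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(M = M, N = N, P = P, precision = precision, recall = recall,
                 f1 = f1, tolerance = tolerance, pairs = pairs),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> M=%d gt, N=%d det, P=%d matched (<= %.2f um)\n",
    x$M, x$N, x$P, x$tolerance))
  cat(sprintf("  precision %.3f  recall %.3f  F1 %.3f\n", x$precision,
              x$recall, x$f1))
  invisible(x)
}

#' Write an evaluation report as JSON (+ optional CSV pair list)
#'
#' @param report an `evaluation_report`.
#' @param json_path output JSON path.
#' @param pairs_csv optional CSV path for the matched pair list.
#' @return `json_path`, invisibly.
#' @export
write_report <- function(report, json_path, pairs_csv = NULL) {
  jsonlite::write_json(report[c("M", "N", "P", "precision", "recall", "f1",
                                "tolerance")],
                       json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(pairs_csv)) {
    utils::write.csv(report$pairs, pairs_csv, row.names = FALSE)
  }
  invisible(json_path)
}
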