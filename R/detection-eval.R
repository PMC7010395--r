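#' Boundary-matching F-measure between two contours
#'
#' The standard boundary-detection quality measure: both curves are
#' rasterised to pixel sets and matched one-to-one by maximum bipartite
#' matching, a candidate pixel matching a truth pixel when they lie within
#' `tol` pixels of each other. Precision is the matched fraction of candidate
#' pixels, recall the matched fraction of truth pixels, and F their harmonic
#' mean. Swapping the two curves exchanges precision and recall and leaves F
#' unchanged.
#'
#' @param candidate,truth [planar_curve()]s (or integer pixel matrices with
#'   columns x, y).
#' @param tol match tolerance in pixels. The conventional default for a
#'   boundary benchmark is 0.0075 x image diagonal; pass that explicitly
#'   when an image geometry is available.
#' @return a list with `f`, `precision`, `recall`, `n_matched`.
#' @export
contour_fmeasure <- function(candidate, truth, tol = 2) {
  cp <- if (inherits(candidate, "planar_curve")) rasterise_curve(candidate)
        else candidate
  tp <- if (inherits(truth, "planar_curve")) rasterise_curve(truth)
        else truth
  if (is.null(cp) || nrow(cp) == 0L) {
    return(list(f = 0, precision = 0, recall = 0, n_matched = 0L))
  }
  if (nrow(tp) == 0L) {
    return(list(f = 0, precision = 0, recall = 0, n_matched = 0L))
  }
  m <- matched_pixels(cp, tp, tol)
  p <- m / nrow(cp)
  r <- m / nrow(tp)
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(f = f, precision = p, recall = r, n_matched = m)
}

# size of the maximum one-to-one matching between two pixel sets under a
# distance tolerance (bipartite maximum matching)
matched_pixels <- function(a, b, tol) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0L)
  d2 <- outer(a[, 1L], b[, 1L], "-")^2 + outer(a[, 2L], b[, 2L], "-")^2
  hits <- which(d2 <= tol^2, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(0L)
  # nodes: 1..nA candidates, nA+1..nA+nB truth
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, nrow(a)), rep(TRUE, nrow(b))),
    edges = as.vector(t(cbind(hits[, 1L], nrow(a) + hits[, 2L]))))
  igraph::max_bipartite_match(g)$matching_size
}

#' Evaluate fin detection over a set of images
#'
#' Sweeps a grid of quality thresholds t: at each t a detection counts as a
#' true positive if its ground-truth quality `f_ground >= t` and it is the
#' highest-scored such detection for its image's fin (one detection per
#' truth, matched greedily by predicted score). Detections are pooled over
#' images and ranked by predicted quality `f_pred` to trace a
#' precision-recall curve; its area is the per-threshold average precision,
#' and the (trapezoidal) mean over the threshold grid is the volume under
#' the PR surface. A value of 1 indicates perfect candidate generation as
#' well as detection.
#'
#' @param detections tibble with columns `image_id`, `f_pred`, `f_ground`.
#' @param truths tibble with column `image_id`, one row per ground-truth fin
#'   (images absent from `truths` contribute only false positives).
#' @param thresholds numeric grid of quality thresholds (non-empty).
#' @return an object of class `detection_evaluation`: list with `ap`
#'   (tibble `t`, `ap`), `pr` (tibble `t`, `recall`, `precision`),
#'   `ap_vol`, and `n_truth`.
#' @export
evaluate_detection <- function(detections, truths, thresholds) {
  if (length(thresholds) == 0L) stop("empty threshold grid")
  thresholds <- sort(as.numeric(thresholds))
  n_truth <- nrow(truths)
  ap <- numeric(length(thresholds))
  pr <- vector("list", length(thresholds))
  for (ti in seq_along(thresholds)) {
    t <- thresholds[ti]
    if (nrow(detections) == 0L) {
      ap[ti] <- 0
      pr[[ti]] <- tibble::tibble(t = t, recall = 0, precision = 1)
      next
    }
    det <- detections[order(-detections$f_pred), , drop = FALSE]
    # one TP per truth: the first (highest-scored) qualifying detection
    is_tp <- logical(nrow(det))
    used <- character(0)
    for (i in seq_len(nrow(det))) {
      id <- as.character(det$image_id[i])
      if (det$f_ground[i] >= t && !(id %in% used) &&
          id %in% as.character(truths$image_id)) {
        is_tp[i] <- TRUE
        used <- c(used, id)
      }
    }
    tp_cum <- cumsum(is_tp)
    prec <- tp_cum / seq_along(is_tp)
    rec <- if (n_truth > 0) tp_cum / n_truth else rep(0, length(is_tp))
    ap[ti] <- if (n_truth > 0) sum(prec[is_tp]) / n_truth else 0
    pr[[ti]] <- tibble::tibble(t = t, recall = rec, precision = prec)
  }
  ap_vol <- if (length(thresholds) == 1L) {
    ap[1L]
  } else {
    dt <- diff(thresholds)
    sum((ap[-1L] + ap[-length(ap)]) / 2 * dt) / sum(dt)
  }
  structure(list(ap = tibble::tibble(t = thresholds, ap = ap),
                 pr = dplyr::bind_rows(pr),
                 ap_vol = ap_vol,
                 n_truth = n_truth),
            class = "detection_evaluation")
}

#' @export
print.detection_evaluation <- function(x, ...) {
  cat(sprintf("<detection_evaluation: %d thresholds, AP_vol = %.4f>\n",
              nrow(x$ap), x$ap_vol))
  print(x$ap)
  invisible(x)
}
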