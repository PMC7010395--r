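# internal constructor without the >=3 point check: boundary arcs between
# adjacent keypoints can legitimately be 2 vertices long
curve_unchecked <- function(points, closed = FALSE) {
  colnames(points) <- c("x", "y")
  structure(list(points = points, closed = isTRUE(closed)),
            class = "planar_curve")
}

#' Generate contour-stroke fin candidates from a region pool
#'
#' Each retained region boundary is resampled, its difference-of-Gaussian
#' corner response computed, and the `n_keypoints` most prominent keypoints
#' found. One stroke candidate is generated per *ordered* keypoint pair
#' (i, j), taking the boundary arc from i to j in traversal direction, so
#' (i, j) and (j, i) are the two complementary arcs of the boundary. With all
#' regions yielding `n` keypoints this gives (n^2 - n) * k candidates;
#' encoding direction is not duplicated here. Regions with fewer than two
#' keypoints contribute none.
#'
#' @param pool a `region_pool` from [select_regions()], or any tibble with
#'   `region_id` and `boundary` (list of closed [planar_curve()]s) columns.
#' @param n_keypoints maximum keypoints per region boundary.
#' @param resample_n boundary resampling resolution before keypointing.
#' @param sigma,m corner-response filter parameters.
#' @return a tibble of class `stroke_set`: `region_id`, `start_idx`,
#'   `end_idx`, `n_vertices` and `path` (list of open [planar_curve()]s).
#' @export
generate_stroke_candidates <- function(pool, n_keypoints = 7L,
                                       resample_n = 128L,
                                       sigma = 1, m = 4) {
  rows <- list()
  for (r in seq_len(nrow(pool))) {
    bnd <- pool$boundary[[r]]
    if (is.null(bnd)) next
    # keypoints are detected on the fixed-resolution resampling, but stroke
    # paths are arcs of the full-resolution region contour
    rc <- resample_curve(bnd, resample_n)
    kps <- find_keypoints(dog_response(rc, sigma, m), n_keypoints)
    if (nrow(kps) < 2L) next
    s_full <- arc_table(bnd)
    L <- s_full[length(s_full)]
    nb <- n_points(bnd)
    kp_arc <- (kps$index - 1L) * L / resample_n
    idx <- sort(unique(vapply(kp_arc, function(a) {
      which.min(abs(s_full[seq_len(nb)] - a))
    }, integer(1))))
    if (length(idx) < 2L) next
    for (i in idx) {
      for (j in idx) {
        if (i == j) next
        arc <- if (i < j) i:j else c(i:nb, 1L:j)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          region_id = pool$region_id[r],
          start_idx = i, end_idx = j,
          n_vertices = length(arc),
          path = list(curve_unchecked(bnd$points[arc, , drop = FALSE])))
      }
    }
  }
  out <- if (length(rows) == 0L) {
    tibble::tibble(region_id = integer(0), start_idx = integer(0),
                   end_idx = integer(0), n_vertices = integer(0),
                   path = list())
  } else {
    dplyr::bind_rows(rows)
  }
  class(out) <- c("stroke_set", class(out))
  out
}

# per-vertex unit tangents (central differences; one-sided at open ends)
curve_tangents <- function(curve) {
  p <- curve$points
  n <- nrow(p)
  if (curve$closed) {
    d <- p[c(2:n, 1L), ] - p[c(n, 1:(n - 1L)), ]
  } else {
    d <- rbind(p[2L, ] - p[1L, ],
               p[3:n, , drop = FALSE] - p[1:(n - 2L), , drop = FALSE],
               p[n, ] - p[n - 1L, ])
  }
  len <- sqrt(rowSums(d^2))
  d / ifelse(len > 0, len, 1)
}

#' Histogram of boundary normals of a stroke
#'
#' Describes stroke shape by the joint distribution of position along the
#' stroke (20 equal arc-length spatial bins) and outward-normal orientation
#' (8 bins over \[0, 2pi)). Normals follow the interior-on-the-left traversal
#' convention, so the histogram depends on encoding direction: reversing the
#' stroke rotates every normal by pi.
#'
#' @param stroke an open [planar_curve()] (or a `stroke_set` row's `path`)
#'   with at least 20 vertices.
#' @param n_spatial,n_orient bin counts.
#' @return an L2-normalised numeric vector of length
#'   `n_spatial * n_orient` (160 by default), spatial-major.
#' @export
normals_histogram <- function(stroke, n_spatial = 20L, n_orient = 8L) {
  p <- stroke$points
  n <- nrow(p)
  if (n < n_spatial) stop("stroke must have at least ", n_spatial, " vertices")
  tg <- curve_tangents(stroke)
  ok <- rowSums(tg^2) > 0.5          # degenerate tangents skipped
  nx <- tg[, 2L]; ny <- -tg[, 1L]    # outward normal (interior left)
  ang <- atan2(ny, nx) %% (2 * pi)
  s <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  L <- s[n]
  sp <- pmin(n_spatial, floor(s / L * n_spatial) + 1L)
  ob <- pmin(n_orient, floor(ang / (2 * pi) * n_orient) + 1L)
  hist <- matrix(0, n_spatial, n_orient)
  for (i in which(ok)) hist[sp[i], ob[i]] <- hist[sp[i], ob[i]] + 1
  v <- as.numeric(t(hist))     # spatial-major: 8 orientations per spatial bin
  l2_normalise(v)
}

l2_normalise <- function(v) {
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v / nrm else v
}

#' Rasterise a curve to integer pixel coordinates
#'
#' Samples the polyline densely (half-pixel steps) and rounds, returning the
#' unique pixels in traversal order.
#'
#' @param curve a [planar_curve()].
#' @return integer matrix with columns `x`, `y`.
#' @export
rasterise_curve <- function(curve) {
  p <- curve$points
  if (curve$closed) p <- rbind(p, p[1L, ])
  n <- nrow(p)
  d <- diff(p)
  # Chebyshev stepping yields thin 8-connected digital lines, matching the
  # pixel density of traced region boundaries
  steps <- pmax(1L, ceiling(pmax(abs(d[, 1L]), abs(d[, 2L]))))
  seg <- rep.int(seq_len(n - 1L), steps + 1L)
  tt <- sequence(steps + 1L, from = 0L) / rep.int(steps, steps + 1L)
  x <- p[seg, 1L] + tt * d[seg, 1L]
  y <- p[seg, 2L] + tt * d[seg, 2L]
  pts <- round(cbind(x, y))
  keep <- !duplicated(complex(real = pts[, 1L], imaginary = pts[, 2L]))
  out <- thin_chain(pts[keep, , drop = FALSE])
  storage.mode(out) <- "integer"
  colnames(out) <- c("x", "y")
  out
}

# reduce a pixel sequence to a thin 8-connected chain: drop pixels that are
# bypassed by an 8-adjacency between their neighbours (sub-pixel wiggles
# otherwise inflate the pixel count of noisy curves)
thin_chain <- function(pts) {
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  keep <- logical(n)
  keep[1L] <- TRUE
  last <- 1L
  i <- 2L
  while (i <= n) {
    if (i < n &&
        max(abs(pts[i, ] - pts[last, ])) <= 1 &&
        max(abs(pts[i + 1L, ] - pts[last, ])) <= 1) {
      i <- i + 1L
      next
    }
    keep[i] <- TRUE
    last <- i
    i <- i + 1L
  }
  pts[keep, , drop = FALSE]
}

#' Non-maximum suppression over scored strokes
#'
#' Greedy suppression by descending predicted quality: a stroke is dropped
#' when its contour overlap with any already-kept stroke exceeds
#' `overlap_thresh`, where overlap is the fraction of matched boundary
#' pixels (one-to-one matching within `tol` pixels) over the smaller of the
#' two pixel sets.
#'
#' @param strokes a tibble with a `path` list-column and a `score` column
#'   (predicted quality).
#' @param overlap_thresh overlap fraction above which a stroke is suppressed.
#' @param tol pixel match tolerance.
#' @return the surviving rows, in descending score order.
#' @export
stroke_nms <- function(strokes, overlap_thresh = 0.2, tol = 2) {
  if (nrow(strokes) == 0L) return(strokes)
  ord <- order(-strokes$score, seq_len(nrow(strokes)))
  pix <- lapply(strokes$path, rasterise_curve)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      m <- matched_pixels(pix[[i]], pix[[j]], tol)
      if (m / min(nrow(pix[[i]]), nrow(pix[[j]])) > overlap_thresh) {
        ok <- FALSE; break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  strokes[kept, , drop = FALSE]
}
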