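#' Planar curves
#'
#' A `planar_curve` is an ordered sequence of 2-D points in pixel units, open
#' or closed, and is the substrate of every shape operation in the package:
#' region boundaries, contour strokes, fin contours and their subsections are
#' all planar curves. For a closed curve the wrap from the last point back to
#' the first is implicit; the first point is never repeated.
#'
#' @param points a numeric matrix or data frame with two columns (x, y), at
#'   least 3 rows, with no two consecutive points identical.
#' @param closed logical; is the curve a closed loop?
#' @return an object of class `planar_curve`: a list with elements `points`
#'   (n x 2 numeric matrix with columns `x`, `y`) and `closed`.
#' @examples
#' sq <- planar_curve(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), closed = TRUE)
#' curve_length(sq)
#' @export
planar_curve <- function(points, closed = FALSE) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("`points` must have two columns (x, y)")
  storage.mode(points) <- "double"
  if (nrow(points) < 3L) stop("a planar curve needs at least 3 points")
  if (anyNA(points) || any(!is.finite(points))) stop("non-finite coordinates")
  d <- diff(points)
  if (any(rowSums(abs(d)) == 0)) stop("consecutive duplicate points")
  if (isTRUE(closed) &&
      all(points[1L, ] == points[nrow(points), ])) {
    stop("closed curves must not repeat the first point as the last")
  }
  colnames(points) <- c("x", "y")
  structure(list(points = points, closed = isTRUE(closed)),
            class = "planar_curve")
}

#' @export
print.planar_curve <- function(x, ...) {
  cat(sprintf("<planar_curve: %d points, %s, length %.3f>\n",
              nrow(x$points), if (x$closed) "closed" else "open",
              curve_length(x)))
  invisible(x)
}

n_points <- function(curve) nrow(curve$points)

#' Total polyline length of a curve
#'
#' Includes the implicit wrap segment for closed curves.
#' @param curve a [planar_curve()].
#' @return total arc length (pixels).
#' @export
curve_length <- function(curve) {
  p <- curve$points
  if (curve$closed) p <- rbind(p, p[1L, ])
  sum(sqrt(rowSums(diff(p)^2)))
}

# Cumulative arc length at each vertex (0 at the first); for closed curves the
# returned vector has n+1 entries, the last being the full loop length.
arc_table <- function(curve) {
  p <- curve$points
  if (curve$closed) p <- rbind(p, p[1L, ])
  c(0, cumsum(sqrt(rowSums(diff(p)^2))))
}

#' Resample a curve uniformly in arc length
#'
#' Places `n_samples` vertices at equal arc-length spacing along the input
#' polyline. Endpoints of open curves are preserved exactly; for closed curves
#' the first vertex is kept as the starting phase and spacing is L/n.
#'
#' @param curve a [planar_curve()].
#' @param n_samples number of output vertices (>= 3).
#' @return a [planar_curve()] with exactly `n_samples` vertices.
#' @export
resample_curve <- function(curve, n_samples) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 3L) stop("n_samples must be >= 3")
  s <- arc_table(curve)
  L <- s[length(s)]
  if (L <= 0) stop("degenerate curve: zero total length")
  p <- curve$points
  if (curve$closed) p <- rbind(p, p[1L, ])
  targets <- if (curve$closed) {
    (seq_len(n_samples) - 1) * L / n_samples
  } else {
    seq(0, L, length.out = n_samples)
  }
  # drop zero-length segments so approx() sees strictly increasing knots
  keep <- c(TRUE, diff(s) > 0)
  x <- stats::approx(s[keep], p[keep, 1L], xout = targets, rule = 2)$y
  y <- stats::approx(s[keep], p[keep, 2L], xout = targets, rule = 2)$y
  if (!curve$closed) {           # exact endpoint preservation
    x[1L] <- p[1L, 1L]; y[1L] <- p[1L, 2L]
    x[n_samples] <- p[nrow(p), 1L]; y[n_samples] <- p[nrow(p), 2L]
  }
  planar_curve(cbind(x, y), closed = curve$closed)
}

# Truncated, renormalised Gaussian kernel (radius 4 sigma, odd length).
gaussian_kernel <- function(sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Convolve a signal with a symmetric kernel under the curve's boundary rule:
# circular wrap for closed curves, odd (anti-symmetric) reflection about the
# end samples for open ones. Odd reflection extrapolates linearly, so
# straight open curves pass through every filter unchanged — no spurious
# corner responses at curve ends.
convolve_signal <- function(x, kernel, closed) {
  n <- length(x)
  r <- (length(kernel) - 1L) %/% 2L
  if (!closed && r > n - 1L) {
    # truncate overly wide kernels so a single reflection fold suffices
    k <- kernel[(length(kernel) + 1L) %/% 2L + seq(-(n - 1L), n - 1L)]
    kernel <- k / sum(k)
    r <- n - 1L
  }
  if (closed) {
    idx <- ((seq(1L - r, n + r) - 1L) %% n) + 1L
    xp <- x[idx]
  } else {
    left <- 2 * x[1L] - x[(r + 1L):2L]
    right <- 2 * x[n] - x[(n - 1L):(n - r)]
    xp <- c(left, x, right)
  }
  out <- stats::filter(xp, kernel, method = "convolution", sides = 2L)
  as.numeric(out[(r + 1L):(r + n)])
}

#' Gaussian smoothing of a planar curve
#'
#' Convolves x(u) and y(u) independently with a zero-mean Gaussian of standard
#' deviation `sigma` (in samples), truncated at 4 sigma and renormalised to
#' unit mass. Closed curves use circular boundary handling; open curves use
#' reflection, which avoids spurious responses at the curve ends.
#'
#' @param curve a [planar_curve()], uniformly resampled.
#' @param sigma filter scale in samples (> 0).
#' @return a smoothed [planar_curve()].
#' @export
gaussian_smooth <- function(curve, sigma) {
  k <- gaussian_kernel(sigma)
  p <- curve$points
  sm <- cbind(convolve_signal(p[, 1L], k, curve$closed),
              convolve_signal(p[, 2L], k, curve$closed))
  structure(list(points = `colnames<-`(sm, c("x", "y")),
                 closed = curve$closed),
            class = "planar_curve")
}

#' Difference-of-Gaussian corner response along a curve
#'
#' The bandpass curvature-saliency signal
#' D(u, sigma) = \[G(u, m sigma) * x - G(u, sigma) * x\]^2 +
#' \[G(u, m sigma) * y - G(u, sigma) * y\]^2,
#' i.e. the squared evolution difference between the curve smoothed at scales
#' `m * sigma` and `sigma`. Large `m` emphasises globally salient corners;
#' small `sigma` keeps their localisation sharp.
#'
#' @param curve a uniformly resampled [planar_curve()].
#' @param sigma filter scale in samples (> 0).
#' @param m scale multiplier (> 0). `m = 1` gives an identically zero
#'   response and raises a warning.
#' @return a `corner_response` object: list with `values` (one non-negative
#'   scalar per vertex), `sigma`, `m`, and `closed`.
#' @export
dog_response <- function(curve, sigma, m) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (m <= 0) stop("m must be > 0")
  if (m == 1) warning("m = 1: DoG response is identically zero")
  fine <- gaussian_smooth(curve, sigma)
  coarse <- gaussian_smooth(curve, m * sigma)
  d <- coarse$points - fine$points
  structure(list(values = d[, 1L]^2 + d[, 2L]^2,
                 sigma = sigma, m = m, closed = curve$closed),
            class = "corner_response")
}

#' @export
print.corner_response <- function(x, ...) {
  cat(sprintf("<corner_response: %d samples, sigma=%g, m=%g, %s>\n",
              length(x$values), x$sigma, x$m,
              if (x$closed) "circular" else "open"))
  invisible(x)
}

# Local maxima (first index of each maximal plateau). Open signals exclude
# plateaus touching either end; closed signals are treated circularly.
local_maxima <- function(v, closed) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  if (closed) {
    if (all(v == v[1L])) return(integer(0))
    # rotate so position 1 is a strict global minimum start; simpler: scan runs
    idx <- integer(0)
    i <- 1L
    prv <- function(i) ((i - 2L) %% n) + 1L
    nxt <- function(i) (i %% n) + 1L
    visited <- logical(n)
    for (start in seq_len(n)) {
      if (visited[start]) next
      # extend plateau of equal values forward
      j <- start
      while (v[nxt(j)] == v[start] && nxt(j) != start) j <- nxt(j)
      run <- if (j >= start) start:j else c(start:n, 1L:j)
      visited[run] <- TRUE
      before <- v[prv(start)]; after <- v[nxt(j)]
      if (v[start] > before && v[start] > after) idx <- c(idx, start)
    }
    sort(idx)
  } else {
    idx <- integer(0)
    i <- 2L
    while (i <= n - 1L) {
      if (v[i] > v[i - 1L]) {
        j <- i
        while (j < n && v[j + 1L] == v[i]) j <- j + 1L
        if (j < n && v[j + 1L] < v[i]) idx <- c(idx, i)
        i <- j + 1L
      } else i <- i + 1L
    }
    idx
  }
}

# Prominence of a local maximum following the findpeaks convention: walk out
# from the peak until a strictly higher value; the reference level is the
# larger of the two interval minima. An interval that reaches the end of an
# open signal contributes a minimum of zero. Closed signals walk circularly.
peak_prominence <- function(v, peak, closed) {
  n <- length(v)
  walk <- function(step) {
    lo <- Inf
    i <- peak
    for (s in seq_len(n - 1L)) {
      i <- if (closed) ((i - 1L + step) %% n) + 1L else i + step
      if (!closed && (i < 1L || i > n)) return(0)   # reached signal end
      if (v[i] > v[peak]) return(lo)
      lo <- min(lo, v[i])
    }
    lo   # closed curve, no strictly higher value: min over the whole loop
  }
  min_l <- walk(-1L)
  min_r <- walk(+1L)
  v[peak] - max(min_l, min_r)
}

#' Prominence-ranked keypoints of a corner response
#'
#' Local maxima of the corner response are ranked by prominence (peak height
#' above the larger of the minima of the two flanking intervals, an interval
#' reaching the end of an open signal counting as zero) and the `n` most
#' prominent are retained. Closed curves are treated as circular signals with
#' no ends. Ties in prominence are broken in favour of the lower vertex index.
#'
#' @param response a `corner_response` from [dog_response()], or a bare
#'   numeric vector (treated as an open signal unless `closed = TRUE`).
#' @param n maximum number of keypoints to keep (>= 1).
#' @param closed only used when `response` is a bare vector.
#' @return a tibble of class `keypoint_set` with columns `index` and
#'   `prominence`, sorted by decreasing prominence. A constant signal yields
#'   zero rows.
#' @export
find_keypoints <- function(response, n, closed = FALSE) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (inherits(response, "corner_response")) {
    v <- response$values
    closed <- response$closed
  } else {
    v <- as.numeric(response)
  }
  peaks <- local_maxima(v, closed)
  if (length(peaks) == 0L) {
    out <- tibble::tibble(index = integer(0), prominence = numeric(0))
    class(out) <- c("keypoint_set", class(out))
    return(out)
  }
  prom <- vapply(peaks, function(p) peak_prominence(v, p, closed), numeric(1))
  ord <- order(-prom, peaks)
  keep <- ord[seq_len(min(n, length(ord)))]
  out <- tibble::tibble(index = peaks[keep], prominence = prom[keep])
  class(out) <- c("keypoint_set", class(out))
  out
}
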