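# Independent brute-force oracles used to pin down the scale-space, matching
# and scoring implementations. These deliberately re-derive everything from
# first principles (naive loops, exhaustive enumeration) and share no code
# with the package internals beyond the public constructors.

# truncated, renormalised Gaussian kernel (kept in sync with the contract:
# radius 4 sigma, unit mass)
oracle_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# O(n k) direct convolution with circular or odd-reflection padding
oracle_convolve <- function(x, sigma, closed) {
  k <- oracle_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  n <- length(x)
  out <- numeric(n)
  fetch <- function(i) {
    if (closed) return(x[((i - 1L) %% n) + 1L])
    if (i < 1L) return(2 * x[1L] - x[2L - i])
    if (i > n) return(2 * x[n] - x[2L * n - i])
    x[i]
  }
  for (i in seq_len(n)) {
    acc <- 0
    for (t in seq(-r, r)) acc <- acc + k[t + r + 1L] * fetch(i - t)
    out[i] <- acc
  }
  out
}

# DoG response via two independent oracle smoothings
oracle_dog <- function(points, sigma, m, closed) {
  gx1 <- oracle_convolve(points[, 1L], sigma, closed)
  gy1 <- oracle_convolve(points[, 2L], sigma, closed)
  gx2 <- oracle_convolve(points[, 1L], m * sigma, closed)
  gy2 <- oracle_convolve(points[, 2L], m * sigma, closed)
  (gx2 - gx1)^2 + (gy2 - gy1)^2
}

# literal interval-walk prominence oracle (findpeaks convention, open ends
# contribute zero minima; closed signals walk circularly)
oracle_prominences <- function(v, closed = FALSE) {
  n <- length(v)
  get <- function(i) v[((i - 1L) %% n) + 1L]
  peaks <- integer(0)
  for (i in seq_len(n)) {
    if (!closed && (i == 1L || i == n)) next
    l <- if (closed) get(i - 1L) else v[i - 1L]
    r <- if (closed) get(i + 1L) else v[i + 1L]
    if (v[i] > l && v[i] > r) peaks <- c(peaks, i)
  }
  # plateaus: also accept the first index of a flat run that drops both sides
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && v[j + 1L] == v[i]) j <- j + 1L
    if (j > i) {
      lv <- if (i > 1L) v[i - 1L] else if (closed) get(i - 1L) else -Inf
      rv <- if (j < n) v[j + 1L] else if (closed) get(j + 1L) else -Inf
      if ((closed || (i > 1L && j < n)) && v[i] > lv && v[i] > rv) {
        peaks <- c(peaks, i)
      }
    }
    i <- j + 1L
  }
  peaks <- sort(unique(peaks))
  prom <- vapply(peaks, function(p) {
    side_min <- function(step) {
      lo <- Inf
      i <- p
      for (s in seq_len(n - 1L)) {
        i <- i + step
        if (!closed && (i < 1L || i > n)) return(0)
        val <- get(i)
        if (val > v[p]) return(lo)
        lo <- min(lo, val)
      }
      lo
    }
    v[p] - max(side_min(-1L), side_min(1L))
  }, numeric(1))
  list(peaks = peaks, prominences = prom)
}

# exact maximum bipartite matching by augmenting paths (Kuhn's algorithm)
oracle_matching_size <- function(a, b, tol) {
  na <- nrow(a); nb <- nrow(b)
  adj <- vector("list", na)
  for (i in seq_len(na)) {
    adj[[i]] <- which((a[i, 1L] - b[, 1L])^2 + (a[i, 2L] - b[, 2L])^2 <=
                        tol^2)
  }
  match_b <- integer(nb)
  try_kuhn <- function(i, seen) {
    for (j in adj[[i]]) {
      if (seen[j]) next
      seen[j] <- TRUE
      if (match_b[j] == 0L || try_kuhn(match_b[j], seen)) {
        match_b[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  size <- 0L
  for (i in seq_len(na)) {
    if (try_kuhn(i, logical(nb))) size <- size + 1L
  }
  size
}

oracle_fmeasure <- function(a, b, tol) {
  m <- oracle_matching_size(a, b, tol)
  p <- m / nrow(a); r <- m / nrow(b)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

# brute-force LNBNN (Eqs-style double summation) over descriptor tibbles
oracle_lnbnn_scores <- function(query, refs, weights = NULL) {
  classes <- sort(unique(refs$individual))
  strata <- unique(paste(query$dtype, query$sigma))
  total <- stats::setNames(numeric(length(classes)), classes)
  for (st in strata) {
    qrows <- which(paste(query$dtype, query$sigma) == st & !query$zero)
    rrows <- which(paste(refs$dtype, refs$sigma) == st & !refs$zero)
    if (length(rrows) == 0L) next
    w <- if (is.null(weights)) 1 else weights[[st]]
    for (qi in qrows) {
      d <- query$vector[[qi]]
      d2 <- vapply(rrows, function(ri) sum((d - refs$vector[[ri]])^2),
                   numeric(1))
      for (ci in seq_along(classes)) {
        inc <- refs$individual[rrows] == classes[ci]
        if (!any(inc) || all(inc)) next
        dc <- min(d2[inc]); do <- min(d2[!inc])
        if (do > dc) total[ci] <- total[ci] + w * (do - dc)
      }
    }
  }
  total
}

# exhaustive PR area from scores + labels: sweep every distinct score as a
# threshold, record (precision, recall), integrate the step curve
oracle_ap <- function(scores, labels) {
  pos <- sum(labels)
  if (pos == 0L) return(NA_real_)
  acc <- 0
  prev_rec <- 0
  for (t in sort(unique(scores), decreasing = TRUE)) {
    sel <- scores >= t
    prec <- sum(labels[sel]) / sum(sel)
    rec <- sum(labels[sel]) / pos
    acc <- acc + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  acc
}

# random jagged closed curve for property tests
random_closed_curve <- function(n = 64L, seed = 1L) {
  set.seed(seed)
  th <- 2 * pi * (seq_len(n) - 1L) / n
  r <- 10 + stats::runif(n, -2, 2)
  planar_curve(cbind(r * cos(th), r * sin(th)), closed = TRUE)
}

# star-shaped closed boundary with `spikes` sharp corners, guaranteed to
# yield at least `spikes` prominent keypoints
star_curve <- function(spikes = 8L, n = 256L, r0 = 30, r1 = 48,
                       centre = c(0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  r <- r0 + (r1 - r0) * (0.5 + 0.5 * cos(spikes * th))
  planar_curve(cbind(centre[1L] + r * cos(th), centre[2L] + r * sin(th)),
               closed = TRUE)
}
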