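#' Region hierarchies
#'
#' A `region_hierarchy` is a tree of nested pixel regions with a level in
#' \[0, 1\] per region, the whole image at the root, in the spirit of an
#' ultrametric contour map: thresholding at any level yields a valid
#' segmentation. Backends are pluggable; any producer emitting nested masks
#' with monotone levels satisfies the contract. The built-in fallback
#' ([build_hierarchy()]) is a gradient-magnitude watershed followed by greedy
#' merging of the weakest region boundary.
#'
#' @param masks list of logical matrices (same dimensions), one per region.
#' @param levels numeric vector in \[0, 1\], one per region.
#' @param parent integer vector of parent indices; `NA` for the root.
#' @return an object of class `region_hierarchy`.
#' @export
region_hierarchy <- function(masks, levels, parent) {
  stopifnot(length(masks) == length(levels),
            length(masks) == length(parent))
  if (length(masks) == 0L) {
    return(structure(list(masks = list(), levels = numeric(0),
                          parent = integer(0)),
                     class = "region_hierarchy"))
  }
  dims <- dim(masks[[1L]])
  h <- structure(list(masks = masks, levels = as.numeric(levels),
                      parent = as.integer(parent), dim = dims),
                 class = "region_hierarchy")
  validate_hierarchy(h)
  h
}

#' @rdname region_hierarchy
#' @param h a `region_hierarchy`.
#' @export
validate_hierarchy <- function(h) {
  if (sum(is.na(h$parent)) != 1L) stop("hierarchy must have exactly one root")
  for (i in seq_along(h$masks)) {
    p <- h$parent[i]
    if (is.na(p)) next
    if (any(h$masks[[i]] & !h$masks[[p]])) {
      stop(sprintf("region %d is not nested inside its parent %d", i, p))
    }
    if (h$levels[i] > h$levels[p] + 1e-12) {
      stop(sprintf("region %d has level above its parent", i))
    }
  }
  invisible(h)
}

#' @export
print.region_hierarchy <- function(x, ...) {
  cat(sprintf("<region_hierarchy: %d regions, %dx%d image>\n",
              length(x$masks), x$dim[1L], x$dim[2L]))
  invisible(x)
}

# ---- low-level raster helpers (shared with the appearance features) --------

# luminance of an RGB array (h x w x 3) or pass-through for a matrix
luminance <- function(image) {
  if (is.matrix(image)) return(image)
  0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
}

# separable Gaussian blur of a matrix, reflected borders
blur_matrix <- function(mat, sigma) {
  k <- gaussian_kernel(sigma)
  tmp <- apply(mat, 2L, convolve_signal, kernel = k, closed = FALSE)
  t(apply(t(tmp), 2L, convolve_signal, kernel = k, closed = FALSE))
}

# central-difference gradient magnitude
gradient_magnitude <- function(mat) {
  h <- nrow(mat); w <- ncol(mat)
  gx <- mat[, c(2:w, w)] - mat[, c(1, 1:(w - 1))]
  gy <- mat[c(2:h, h), ] - mat[c(1, 1:(h - 1)), ]
  sqrt(gx^2 + gy^2)
}

# ---- fallback hierarchy builder --------------------------------------------

#' Build a region hierarchy from an image
#'
#' Adapter entry point for region-hierarchy backends. The default backend is
#' a deterministic stand-in built here: the gradient magnitude of the blurred
#' luminance is segmented into basins by watershed, and basins are then merged
#' greedily by increasing mean boundary gradient, producing a merge tree whose
#' (monotonised) merge strengths become hierarchy levels in \[0, 1\]. Any
#' external backend can be plugged in through `backend`, and must return a
#' valid [region_hierarchy()]; failures surface as errors, never as a partial
#' hierarchy.
#'
#' @param image RGB array (h x w x 3) or grayscale matrix, values in \[0, 1\].
#' @param backend `"watershed"` (built-in fallback) or a function
#'   `image -> region_hierarchy`.
#' @param blur_sigma pre-smoothing scale in pixels.
#' @param tolerance watershed merging tolerance, as a fraction of the
#'   gradient range (suppresses basins from shallow gradient minima).
#' @return a [region_hierarchy()].
#' @export
build_hierarchy <- function(image, backend = "watershed",
                            blur_sigma = 1.5, tolerance = 0.05) {
  if (is.function(backend)) {
    h <- backend(image)
    if (!inherits(h, "region_hierarchy")) {
      stop("hierarchy backend did not return a region_hierarchy")
    }
    validate_hierarchy(h)
    return(h)
  }
  lum <- luminance(image)
  if (length(lum) == 0L) stop("empty image")
  g <- gradient_magnitude(blur_matrix(lum, blur_sigma))
  rng <- diff(range(g))
  full <- matrix(TRUE, nrow(lum), ncol(lum))
  if (rng == 0) {   # constant image: single root region
    return(region_hierarchy(list(full), 1, NA_integer_))
  }
  surface <- (max(g) - g) / rng + 1e-6   # basins at gradient minima
  labels <- EBImage::watershed(surface, tolerance = tolerance)
  labels <- matrix(as.integer(labels), nrow(lum), ncol(lum))
  labels[labels == 0L] <- max(labels) + 1L   # watershed lines: own basin ok
  labels <- match(labels, sort(unique(as.vector(labels))))
  dim(labels) <- dim(lum)
  labels <- snap_labels(labels, lum)
  merge_tree_hierarchy(labels, g)
}

# Boundary snap: basins inherit the gradient crest, which straddles the true
# edge; reassign pixels adjacent to another basin to whichever neighbouring
# basin's mean (unblurred) luminance matches the pixel best. Deterministic.
snap_labels <- function(labels, lum, iters = 2L) {
  h <- nrow(labels); w <- ncol(labels)
  for (it in seq_len(iters)) {
    mu <- vapply(split(as.vector(lum), as.vector(labels)), mean, numeric(1))
    nb_diff <- matrix(FALSE, h, w)
    nb_diff[, -w] <- nb_diff[, -w] | labels[, -w] != labels[, -1L]
    nb_diff[, -1L] <- nb_diff[, -1L] | labels[, -w] != labels[, -1L]
    nb_diff[-h, ] <- nb_diff[-h, ] | labels[-h, ] != labels[-1L, ]
    nb_diff[-1L, ] <- nb_diff[-1L, ] | labels[-h, ] != labels[-1L, ]
    idx <- which(nb_diff)
    if (length(idx) == 0L) break
    new_lab <- labels
    for (p in idx) {
      r <- ((p - 1L) %% h) + 1L; c <- ((p - 1L) %/% h) + 1L
      cand <- labels[p]
      best <- abs(lum[p] - mu[[as.character(labels[p])]])
      for (d in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
        if (d[1L] < 1L || d[1L] > h || d[2L] < 1L || d[2L] > w) next
        lb <- labels[d[1L], d[2L]]
        if (lb == cand) next
        err <- abs(lum[p] - mu[[as.character(lb)]])
        if (err < best - 1e-12 || (err < best + 1e-12 && lb < cand)) {
          best <- err; cand <- lb
        }
      }
      new_lab[p] <- cand
    }
    if (all(new_lab == labels)) break
    labels <- new_lab
  }
  # a snap could in principle empty a basin; relabel compactly
  labels <- match(labels, sort(unique(as.vector(labels))))
  dim(labels) <- c(h, w)
  labels
}

# Greedy boundary-strength merge tree over a label partition. Boundary
# strength between two regions is the mean gradient over their shared
# adjacent pixel pairs; merging proceeds from the weakest boundary upward and
# merge strengths are monotonised into levels (leaves at 0, root at 1).
merge_tree_hierarchy <- function(labels, g) {
  nb <- max(labels)
  h <- nrow(labels); w <- ncol(labels)
  masks <- lapply(seq_len(nb), function(i) labels == i)
  if (nb == 1L) {
    return(region_hierarchy(masks, 1, NA_integer_))
  }
  # accumulate boundary sum/count per adjacent region pair (mean = sum/n)
  pair_a <- integer(0); pair_b <- integer(0)
  pair_s <- numeric(0); pair_n <- numeric(0)
  add_edges <- function(a, b, wts) {
    a2 <- pmin(a, b); b2 <- pmax(a, b)
    keep <- a2 != b2
    if (!any(keep)) return(invisible())
    key <- paste(a2[keep], b2[keep])
    s <- vapply(split(wts[keep], key), sum, numeric(1))
    n <- vapply(split(wts[keep], key), length, integer(1))
    ab <- do.call(rbind, strsplit(names(s), " ", fixed = TRUE))
    pair_a <<- c(pair_a, as.integer(ab[, 1L]))
    pair_b <<- c(pair_b, as.integer(ab[, 2L]))
    pair_s <<- c(pair_s, as.numeric(s))
    pair_n <<- c(pair_n, as.numeric(n))
  }
  gh <- (g[, -w] + g[, -1L]) / 2
  add_edges(as.vector(labels[, -w]), as.vector(labels[, -1L]), as.vector(gh))
  gv <- (g[-h, ] + g[-1L, ]) / 2
  add_edges(as.vector(labels[-h, ]), as.vector(labels[-1L, ]), as.vector(gv))

  collapse_pairs <- function() {
    key <- paste(pair_a, pair_b)
    s <- vapply(split(pair_s, key), sum, numeric(1))
    n <- vapply(split(pair_n, key), sum, numeric(1))
    ab <- do.call(rbind, strsplit(names(s), " ", fixed = TRUE))
    pair_a <<- as.integer(ab[, 1L]); pair_b <<- as.integer(ab[, 2L])
    pair_s <<- as.numeric(s); pair_n <<- as.numeric(n)
  }
  collapse_pairs()

  active <- seq_len(nb)           # node ids currently mergeable
  node_mask <- masks
  parent <- rep(NA_integer_, nb)
  strengths <- numeric(0)
  while (length(active) > 1L) {
    if (length(pair_a) == 0L) {
      stop("internal: disconnected region adjacency")
    }
    means <- pair_s / pair_n
    best <- order(means, pair_a, pair_b)[1L]   # deterministic tie-break
    ab <- c(pair_a[best], pair_b[best])
    new_id <- length(node_mask) + 1L
    node_mask[[new_id]] <- node_mask[[ab[1L]]] | node_mask[[ab[2L]]]
    parent[ab] <- new_id
    parent[new_id] <- NA_integer_
    strengths <- c(strengths, means[best])
    # rewire edges touching a or b to new_id, drop the merged pair
    drop <- (pair_a %in% ab) & (pair_b %in% ab)
    pair_a <- pair_a[!drop]; pair_b <- pair_b[!drop]
    pair_s <- pair_s[!drop]; pair_n <- pair_n[!drop]
    pair_a[pair_a %in% ab] <- new_id
    pair_b[pair_b %in% ab] <- new_id
    flip <- pair_a > pair_b
    tmp <- pair_a[flip]; pair_a[flip] <- pair_b[flip]; pair_b[flip] <- tmp
    collapse_pairs()
    active <- c(setdiff(active, ab), new_id)
  }
  n_all <- length(node_mask)
  levels <- numeric(n_all)
  if (length(strengths) > 0L) {
    mono <- cummax(strengths)
    span <- if (max(mono) > 0) max(mono) else 1
    levels[(nb + 1L):n_all] <- pmax(mono / span, 1e-9)
  }
  region_hierarchy(node_mask, levels, parent)
}

# ---- region selection ------------------------------------------------------

#' Select a ranked pool of candidate regions from a hierarchy
#'
#' Descends the hierarchy by decreasing level to a pool of at most
#' `pool_size` unique regions, rejects regions too small to represent a fin
#' (`min_area_frac` of image area) or too similar to an already-kept region
#' (mask IoU above `dup_iou`), then retains the `k` highest-ranked survivors.
#'
#' @param h a [region_hierarchy()].
#' @param pool_size maximum number of unique regions considered.
#' @param k number of regions retained.
#' @param min_area_frac minimum region area as a fraction of image area.
#' @param dup_iou IoU above which a region is a duplicate of a kept one.
#' @param trace_boundaries if `TRUE` (default) attach the closed boundary
#'   curve of each kept region.
#' @return a tibble of class `region_pool` with columns `region_id`, `level`,
#'   `area`, `mask` (list of logical matrices) and `boundary` (list of closed
#'   [planar_curve()]s, or `NULL`s when not traced).
#' @export
select_regions <- function(h, pool_size = 200L, k = 12L,
                           min_area_frac = 0.001, dup_iou = 0.95,
                           trace_boundaries = TRUE) {
  empty <- tibble::tibble(region_id = integer(0), level = numeric(0),
                          area = numeric(0), mask = list(), boundary = list())
  class(empty) <- c("region_pool", class(empty))
  if (length(h$masks) == 0L) return(empty)
  areas <- vapply(h$masks, sum, numeric(1))
  ord <- order(-h$levels, -areas, seq_along(h$masks))
  ord <- ord[seq_len(min(pool_size, length(ord)))]
  img_area <- prod(h$dim)
  kept <- integer(0)
  for (i in ord) {
    if (areas[i] < min_area_frac * img_area) next
    dup <- FALSE
    for (j in kept) {
      inter <- sum(h$masks[[i]] & h$masks[[j]])
      uni <- areas[i] + areas[j] - inter
      if (uni > 0 && inter / uni > dup_iou) { dup <- TRUE; break }
    }
    if (dup) next
    kept <- c(kept, i)
    if (length(kept) >= k) break
  }
  if (length(kept) == 0L) return(empty)
  boundaries <- if (trace_boundaries) {
    lapply(kept, function(i) tryCatch(region_boundary(h$masks[[i]]),
                                      error = function(e) NULL))
  } else {
    rep(list(NULL), length(kept))
  }
  out <- tibble::tibble(region_id = kept,
                        level = h$levels[kept],
                        area = areas[kept],
                        mask = h$masks[kept],
                        boundary = boundaries)
  class(out) <- c("region_pool", class(out))
  out
}

# ---- boundary tracing ------------------------------------------------------

# 8-connected component check via flood fill
single_component <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0L) return(FALSE)
  # fast path: 4-connected in one piece implies 8-connected in one piece
  if (max(EBImage::bwlabel(mask * 1)) == 1L) return(TRUE)
  h <- nrow(mask)
  nmask <- length(mask)
  seen <- logical(nmask)
  queue <- integer(length(idx))      # preallocated BFS queue
  queue[1L] <- idx[1L]
  seen[idx[1L]] <- TRUE
  head <- 1L; tail <- 1L
  offs <- c(-1L, 1L, -h, h, -h - 1L, -h + 1L, h - 1L, h + 1L)
  while (head <= tail) {
    cur <- queue[head]; head <- head + 1L
    row <- ((cur - 1L) %% h) + 1L
    for (o in offs) {
      nb <- cur + o
      if (nb < 1L || nb > nmask) next
      nrow_ <- ((nb - 1L) %% h) + 1L
      if (abs(nrow_ - row) > 1L) next          # column wrap guard
      if (mask[nb] && !seen[nb]) {
        seen[nb] <- TRUE
        tail <- tail + 1L
        queue[tail] <- nb
      }
    }
  }
  tail == length(idx)
}

#' Trace the closed boundary of a pixel mask
#'
#' Moore-neighbour tracing of a single 8-connected component, one vertex per
#' boundary pixel, oriented so that the signed (shoelace) area of the
#' returned polygon is positive; reversing the traversal is therefore
#' detectable from the sign of the area.
#'
#' @param mask logical matrix, a single connected component of at least a few
#'   pixels.
#' @return a closed [planar_curve()] with vertices at pixel centres, `(x, y)`
#'   = (column, row).
#' @export
region_boundary <- function(mask) {
  if (!any(mask)) stop("empty mask")
  if (!single_component(mask)) stop("mask has multiple connected components")
  h <- nrow(mask); w <- ncol(mask)
  at <- function(r, c) r >= 1L && r <= h && c >= 1L && c <= w && mask[r, c]
  # start: first foreground pixel in column-major order
  start_idx <- which(mask)[1L]
  sr <- ((start_idx - 1L) %% h) + 1L
  sc <- ((start_idx - 1L) %/% h) + 1L
  # Moore neighbourhood in clockwise order starting from W (dr, dc)
  moor <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
                c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  path_r <- integer(0); path_c <- integer(0)
  cr <- sr; cc <- sc
  backtrack <- 1L   # came from the West
  first_dir <- NA_integer_
  max_steps <- 4L * h * w + 8L
  for (step in seq_len(max_steps)) {
    path_r <- c(path_r, cr); path_c <- c(path_c, cc)
    found <- FALSE
    probe <- backtrack
    for (s in seq_len(8L)) {
      probe <- (probe %% 8L) + 1L
      nr <- cr + moor[probe, 1L]; nc <- cc + moor[probe, 2L]
      if (at(nr, nc)) {
        backtrack <- ((probe + 3L) %% 8L) + 1L   # points back to current pixel
        cr <- nr; cc <- nc
        found <- TRUE
        break
      }
    }
    if (!found) break   # isolated pixel: no neighbours
    if (cr == sr && cc == sc) break   # loop closed at the start pixel
    if (step == 1L) first_dir <- probe
  }
  if (length(path_r) < 3L) stop("mask too small to form a boundary curve")
  pts <- cbind(x = as.numeric(path_c), y = as.numeric(path_r))
  # deduplicate consecutive repeats (cannot occur, but keep the constructor
  # honest) and enforce positive signed area
  crv <- planar_curve(pts, closed = TRUE)
  if (signed_area(crv) < 0) {
    crv <- planar_curve(pts[rev(seq_len(nrow(pts))), , drop = FALSE],
                        closed = TRUE)
  }
  crv
}

#' Signed (shoelace) area of a closed curve
#'
#' @param curve a closed [planar_curve()].
#' @return the signed area; the fixed traversal convention of
#'   [region_boundary()] yields a positive value.
#' @export
signed_area <- function(curve) {
  if (!curve$closed) stop("signed area requires a closed curve")
  p <- curve$points
  q <- p[c(2:nrow(p), 1L), ]
  sum(p[, 1L] * q[, 2L] - q[, 1L] * p[, 2L]) / 2
}
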