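#' Opponent colour channels of an RGB image
#'
#' O1 = (R - G) / sqrt(2), O2 = (R + G - 2B) / sqrt(6),
#' O3 = (R + G + B) / sqrt(3). O3 carries intensity; O1/O2 carry
#' colour-opponent information largely invariant to intensity shifts.
#'
#' @param image RGB array (h x w x 3) in \[0, 1\]; a grayscale matrix is
#'   promoted to R = G = B.
#' @return list of three matrices `o1`, `o2`, `o3`.
#' @export
opponent_channels <- function(image) {
  if (is.matrix(image)) image <- array(rep(image, 3L), c(dim(image), 3L))
  r <- image[, , 1L]; g <- image[, , 2L]; b <- image[, , 3L]
  list(o1 = (r - g) / sqrt(2),
       o2 = (r + g - 2 * b) / sqrt(6),
       o3 = (r + g + b) / sqrt(3))
}

# integral image supporting clipped square-window sums
integral_image <- function(mat) {
  ii <- apply(mat, 2L, cumsum)
  ii <- t(apply(ii, 1L, cumsum))
  rbind(0, cbind(0, ii))
}

# window sums over [r - half, r + half] x [c - half, c + half], clipped;
# rows/cols are vectors, returns list(sum, area)
window_sum <- function(ii, rows, cols, half, h, w) {
  r1 <- pmax(rows - half, 1L); r2 <- pmin(rows + half, h)
  c1 <- pmax(cols - half, 1L); c2 <- pmin(cols + half, w)
  s <- ii[cbind(r2 + 1L, c2 + 1L)] - ii[cbind(r1, c2 + 1L)] -
       ii[cbind(r2 + 1L, c1)] + ii[cbind(r1, c1)]
  list(sum = s, area = (r2 - r1 + 1) * (c2 - c1 + 1))
}

# dense local descriptor: per opponent channel, window mean and standard
# deviation at one patch size -> 6 dims per (pixel, size)
patch_descriptors <- function(channels, rows, cols, patch_size) {
  h <- nrow(channels$o1); w <- ncol(channels$o1)
  half <- patch_size %/% 2L
  out <- matrix(0, length(rows), 6L)
  k <- 1L
  for (ch in channels) {
    ws <- window_sum(integral_image(ch), rows, cols, half, h, w)
    ws2 <- window_sum(integral_image(ch^2), rows, cols, half, h, w)
    mu <- ws$sum / ws$area
    va <- pmax(ws2$sum / ws$area - mu^2, 0)
    out[, k] <- mu
    out[, k + 1L] <- sqrt(va)
    k <- k + 2L
  }
  out
}

#' Train a visual dictionary for the appearance channel
#'
#' Learns `n_words` k-means centroids over dense opponent-colour patch
#' descriptors sampled from the supplied training images at every patch
#' size. Seeded and deterministic.
#'
#' @param images list of RGB arrays (or grayscale matrices).
#' @param n_words dictionary size.
#' @param patch_sizes patch sizes in pixels.
#' @param n_sample descriptors sampled per (image, patch size).
#' @param seed RNG seed.
#' @return an object of class `visual_dictionary`: list with `centers`
#'   (n_words x 6), `patch_sizes`, `seed`.
#' @export
train_visual_dictionary <- function(images, n_words = 20L,
                                    patch_sizes = c(16L, 24L, 32L, 40L),
                                    n_sample = 500L, seed = 1L) {
  descs <- list()
  set.seed(seed)
  for (img in images) {
    ch <- opponent_channels(img)
    h <- nrow(ch$o1); w <- ncol(ch$o1)
    n <- min(n_sample, h * w)
    idx <- sample.int(h * w, n)
    rows <- ((idx - 1L) %% h) + 1L
    cols <- ((idx - 1L) %/% h) + 1L
    for (ps in patch_sizes) {
      descs[[length(descs) + 1L]] <- patch_descriptors(ch, rows, cols, ps)
    }
  }
  mat <- unique(do.call(rbind, descs))
  k <- min(n_words, nrow(mat))
  km <- stats::kmeans(mat, centers = k, nstart = 5L, iter.max = 50L)
  centers <- km$centers
  if (k < n_words) {   # degenerate inputs: pad with repeats to keep the
    centers <- centers[rep(seq_len(k), length.out = n_words), , drop = FALSE]
  }                    # 20-word contract
  structure(list(centers = unname(centers), patch_sizes = patch_sizes,
                 seed = seed),
            class = "visual_dictionary")
}

#' Bag-of-visual-words appearance histogram around a stroke
#'
#' Dense opponent-colour patch descriptors are computed at every patch size
#' for each pixel within `band` pixels of the rasterised stroke (subsampled
#' by `stride`), hard-assigned to the nearest dictionary word, and
#' accumulated into an L2-normalised histogram. The histogram depends only
#' on the pixel set of the stroke, so it is independent of encoding
#' direction.
#'
#' @param image RGB array or grayscale matrix.
#' @param stroke an open [planar_curve()].
#' @param dict a [train_visual_dictionary()] object.
#' @param band half-width of the pixel band around the stroke.
#' @param stride subsampling step over band pixels.
#' @return an L2-normalised numeric vector of length `nrow(dict$centers)`.
#' @export
appearance_bag <- function(image, stroke, dict, band = 4L, stride = 1L) {
  ch <- opponent_channels(image)
  h <- nrow(ch$o1); w <- ncol(ch$o1)
  pix <- rasterise_curve(stroke)
  # band: all pixels within Euclidean distance `band` of a stroke pixel
  offs <- expand.grid(dx = -band:band, dy = -band:band)
  offs <- offs[offs$dx^2 + offs$dy^2 <= band^2, ]
  cand_x <- rep(pix[, 1L], each = nrow(offs)) + offs$dx
  cand_y <- rep(pix[, 2L], each = nrow(offs)) + offs$dy
  ok <- cand_x >= 1L & cand_x <= w & cand_y >= 1L & cand_y <= h
  cand <- unique(cbind(cand_x[ok], cand_y[ok]))
  if (nrow(cand) == 0L) {
    warning("stroke band lies outside the image; zero appearance histogram")
    return(numeric(nrow(dict$centers)))
  }
  cand <- cand[order(cand[, 2L], cand[, 1L]), , drop = FALSE]
  cand <- cand[seq(1L, nrow(cand), by = stride), , drop = FALSE]
  counts <- numeric(nrow(dict$centers))
  for (ps in dict$patch_sizes) {
    d <- patch_descriptors(ch, cand[, 2L], cand[, 1L], ps)
    # squared distance to each centre: ||d||^2 - 2 d.c + ||c||^2
    cc <- dict$centers
    d2 <- outer(rowSums(d^2), rowSums(cc^2), "+") - 2 * d %*% t(cc)
    words <- max.col(-d2, ties.method = "first")
    tab <- tabulate(words, nbins = nrow(cc))
    counts <- counts + tab
  }
  l2_normalise(counts)
}

#' Assemble 180-dimensional stroke feature vectors
#'
#' Concatenates the L2-normalised 20-word appearance bag and the
#' L2-normalised 20 x 8 histogram of boundary normals for each stroke.
#' Strokes too short for the normals histogram get a zero shape component.
#'
#' @param image RGB array or grayscale matrix.
#' @param strokes a `stroke_set` tibble (needs a `path` list-column).
#' @param dict a [train_visual_dictionary()] object.
#' @inheritParams appearance_bag
#' @return numeric matrix, one row per stroke, 180 columns.
#' @export
stroke_features <- function(image, strokes, dict, band = 4L, stride = 1L) {
  n <- nrow(strokes)
  out <- matrix(0, n, nrow(dict$centers) + 160L)
  for (i in seq_len(n)) {
    pth <- strokes$path[[i]]
    app <- appearance_bag(image, pth, dict, band = band, stride = stride)
    shp <- if (nrow(pth$points) >= 20L) normals_histogram(pth)
           else numeric(160L)
    out[i, ] <- c(app, shp)
  }
  out
}
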