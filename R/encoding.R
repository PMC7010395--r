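#' Fin contours
#'
#' A detected fin is carried forward as an open contour resampled to a fixed
#' resolution (1024 vertices by default) so that filter scales are
#' comparable across fins of different image sizes.
#'
#' @param curve an open [planar_curve()].
#' @param image_id identifier of the source image.
#' @param n_samples resampling resolution.
#' @param refined has the edge-refinement hook been applied?
#' @return an object of class `fin_contour`: list with `path` (open
#'   [planar_curve()] of `n_samples` vertices), `image_id`, `refined`.
#' @export
fin_contour <- function(curve, image_id = NA_character_,
                        n_samples = 1024L, refined = FALSE) {
  if (curve$closed) stop("a fin contour must be an open curve")
  structure(list(path = resample_curve(curve, n_samples),
                 image_id = as.character(image_id),
                 refined = isTRUE(refined)),
            class = "fin_contour")
}

#' @export
print.fin_contour <- function(x, ...) {
  cat(sprintf("<fin_contour: %d vertices, image %s%s>\n",
              n_points(x$path), x$image_id,
              if (x$refined) ", refined" else ""))
  invisible(x)
}

#' Edge-refinement hook
#'
#' Sub-pixel refinement of a detected contour against the image (e.g. border
#' matting in a narrow strip around the boundary) is a pluggable stage. The
#' default hook is the identity: the contour passes through unchanged. A
#' plugged refiner receives `(image, curve)` and must return an open curve
#' with the same endpoints semantics.
#'
#' @param image RGB array or grayscale matrix.
#' @param contour an open [planar_curve()].
#' @param hook `NULL` (identity) or a function `(image, curve) -> curve`.
#' @return the (possibly refined) contour.
#' @export
refine_contour <- function(image, contour, hook = NULL) {
  if (is.null(hook)) return(contour)
  out <- hook(image, contour)
  if (!inherits(out, "planar_curve") || out$closed) {
    stop("refinement hook must return an open planar_curve")
  }
  out
}

#' Salient keypoints of a fin contour
#'
#' Corner response at a coarse bandpass setting (sigma = 2, m = 8 on the
#' 1024-vertex contour) and prominence ranking pick out up to `n` stable
#' locations (notches, the tip, bumps) that bound descriptor subsections.
#'
#' @param fin a [fin_contour()].
#' @param n maximum number of keypoints.
#' @param sigma,m corner-response parameters.
#' @return a `keypoint_set` tibble (possibly fewer than `n` rows).
#' @export
extract_fin_keypoints <- function(fin, n = 50L, sigma = 2, m = 8) {
  find_keypoints(dog_response(fin$path, sigma, m), n)
}

#' Generate contour subsections between keypoint pairs
#'
#' One subsection per unordered keypoint pair: the single arc of the open
#' fin contour connecting the two keypoints, resampled to `n_samples`
#' vertices. With 50 keypoints this yields choose(50, 2) = 1225 subsections.
#' For reference encodings the set is doubled with reversed paths so that
#' query-time matching need not consider direction.
#'
#' @param fin a [fin_contour()].
#' @param keypoints a `keypoint_set` from [extract_fin_keypoints()].
#' @param both_directions also emit reversed paths?
#' @param n_samples per-subsection resampling resolution.
#' @return a tibble of class `subsection_set`: `start_kp`, `end_kp` (vertex
#'   indices), `start_pos`, `end_pos` (arc-length fractions along the fin),
#'   `p` (subsection length as a fraction of fin length), `direction`
#'   (`"fwd"`/`"rev"`), `path` (list of open [planar_curve()]s).
#' @export
generate_subsections <- function(fin, keypoints, both_directions = FALSE,
                                 n_samples = 256L) {
  empty <- tibble::tibble(start_kp = integer(0), end_kp = integer(0),
                          start_pos = numeric(0), end_pos = numeric(0),
                          p = numeric(0), direction = character(0),
                          path = list())
  class(empty) <- c("subsection_set", class(empty))
  if (nrow(keypoints) < 2L) return(empty)
  idx <- sort(unique(keypoints$index))
  s <- arc_table(fin$path)
  L <- s[length(s)]
  pts <- fin$path$points
  nk <- length(idx)
  n_sub <- nk * (nk - 1L) %/% 2L * (if (both_directions) 2L else 1L)
  start_kp <- integer(n_sub); end_kp <- integer(n_sub)
  start_pos <- numeric(n_sub); end_pos <- numeric(n_sub)
  pfrac <- numeric(n_sub); direction <- character(n_sub)
  paths <- vector("list", n_sub)
  k <- 0L
  for (a in seq_len(nk - 1L)) {
    for (b in (a + 1L):nk) {
      i <- idx[a]; j <- idx[b]
      arc <- curve_unchecked(pts[i:j, , drop = FALSE])
      path <- resample_curve(arc, n_samples)
      p <- (s[j] - s[i]) / L
      k <- k + 1L
      start_kp[k] <- i; end_kp[k] <- j
      start_pos[k] <- s[i] / L; end_pos[k] <- s[j] / L
      pfrac[k] <- p; direction[k] <- "fwd"; paths[[k]] <- path
      if (both_directions) {
        k <- k + 1L
        start_kp[k] <- j; end_kp[k] <- i
        start_pos[k] <- s[i] / L; end_pos[k] <- s[j] / L
        pfrac[k] <- p; direction[k] <- "rev"
        paths[[k]] <- curve_unchecked(
          path$points[rev(seq_len(n_samples)), , drop = FALSE])
      }
    }
  }
  out <- tibble::tibble(start_kp = start_kp, end_kp = end_kp,
                        start_pos = start_pos, end_pos = end_pos,
                        p = pfrac, direction = direction, path = paths)
  class(out) <- c("subsection_set", class(out))
  out
}

#' DoG-norm biometric descriptor of a subsection
#'
#' The per-vertex difference-of-Gaussian corner response of the subsection
#' (open-curve boundary handling, scale multiplier `m = 2`), L2-normalised.
#' Rotation and translation of the subsection leave the response unchanged,
#' so the descriptor is rigid-motion invariant. A straight (zero-response)
#' subsection yields a flagged zero vector, excluded from matching.
#'
#' @param path an open [planar_curve()] with the subsection's fixed
#'   resampling (256 vertices).
#' @param sigma filter scale, one of the configured descriptor scales.
#' @param m scale multiplier.
#' @return list with `vector` (length = vertex count), `zero` (flag),
#'   `dtype = "dogn"`, `sigma`.
#' @export
dogn_descriptor <- function(path, sigma, m = 2) {
  v <- dog_response(path, sigma, m)$values
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-12) {
    list(vector = numeric(length(v)), zero = TRUE, dtype = "dogn",
         sigma = sigma)
  } else {
    list(vector = v / nrm, zero = FALSE, dtype = "dogn", sigma = sigma)
  }
}

# rigidly move a point matrix so the start->end chord lies on +x, start at 0
align_to_chord <- function(p) {
  p <- sweep(p, 2L, p[1L, ])
  chord <- p[nrow(p), ]
  len <- sqrt(sum(chord^2))
  if (len < 1e-12) stop("coincident subsection endpoints: alignment undefined")
  ct <- chord[1L] / len; st <- chord[2L] / len
  cbind(p[, 1L] * ct + p[, 2L] * st,
        -p[, 1L] * st + p[, 2L] * ct)
}

# sum of z components of successive tangent cross products (bending sign)
mean_turn <- function(p) {
  d <- diff(p)
  n <- nrow(d)
  if (n < 2L) return(0)
  sum(d[-n, 1L] * d[-1L, 2L] - d[-n, 2L] * d[-1L, 1L])
}

#' Chord-aligned boundary-normal descriptor of a subsection
#'
#' The subsection is rigidly transformed so its start-to-end chord lies on
#' the +x axis with the start at the origin (removing rotation and
#' translation), then Gaussian-smoothed at `sigma`. In the default variant
#' the unit normals of the smoothed curve are computed per vertex and their
#' two components concatenated into a 2n vector; `variant =
#' "smoothed_coords"` instead concatenates the smoothed coordinates
#' themselves. The residual reflection ambiguity of chord alignment is
#' resolved by requiring a non-negative net turn (the curve is mirrored
#' about the chord when needed). The result is L2-normalised.
#'
#' @inheritParams dogn_descriptor
#' @param variant `"unit_normals"` (default) or `"smoothed_coords"`.
#' @return list with `vector` (length 2n), `zero = FALSE`,
#'   `dtype = "normal"`, `sigma`.
#' @export
normal_descriptor <- function(path, sigma,
                              variant = c("unit_normals", "smoothed_coords")) {
  variant <- match.arg(variant)
  p <- align_to_chord(path$points)
  if (mean_turn(p) < 0) p[, 2L] <- -p[, 2L]
  crv <- gaussian_smooth(curve_unchecked(p), sigma)
  if (variant == "unit_normals") {
    tg <- curve_tangents(crv)
    v <- c(tg[, 2L], -tg[, 1L])       # (nx, ny) concatenated
  } else {
    v <- c(crv$points[, 1L], crv$points[, 2L])
  }
  list(vector = l2_normalise(v), zero = FALSE, dtype = "normal",
       sigma = sigma)
}

#' Encode a fin contour into a multi-scale descriptor set
#'
#' Runs keypointing, subsection generation, and descriptor computation for
#' every combination of descriptor type and filter scale. Query images are
#' encoded in one direction; reference images in both, so that matching
#' never needs to compare directions.
#'
#' @param fin a [fin_contour()].
#' @param scales filter scales.
#' @param types descriptor types, subset of `c("dogn", "normal")`.
#' @param both_directions encode reversed subsections too (references).
#' @param n_keypoints maximum keypoints bounding subsections.
#' @param n_samples per-subsection resampling resolution.
#' @param individual optional individual label (for reference sets).
#' @param normal_variant passed to [normal_descriptor()].
#' @return a tibble of class `descriptor_set`: subsection metadata columns
#'   plus `dtype`, `sigma`, `zero` and a `vector` list-column, with
#'   attributes `image_id` and `l_n`.
#' @export
encode_fin <- function(fin, scales = c(1, 2, 4, 8),
                       types = c("dogn", "normal"),
                       both_directions = FALSE,
                       n_keypoints = 50L, n_samples = 256L,
                       individual = NA_character_,
                       normal_variant = "unit_normals") {
  kps <- extract_fin_keypoints(fin, n = n_keypoints)
  subs <- generate_subsections(fin, kps, both_directions = both_directions,
                               n_samples = n_samples)
  n_out <- nrow(subs) * length(scales) * length(types)
  sub_id <- integer(n_out); dtype <- character(n_out)
  sigma <- numeric(n_out); zero <- logical(n_out)
  vectors <- vector("list", n_out)
  k <- 0L
  for (si in seq_len(nrow(subs))) {
    pth <- subs$path[[si]]
    for (ty in types) {
      for (sg in scales) {
        d <- if (ty == "dogn") {
          dogn_descriptor(pth, sg)
        } else {
          normal_descriptor(pth, sg, variant = normal_variant)
        }
        k <- k + 1L
        sub_id[k] <- si; dtype[k] <- ty; sigma[k] <- sg
        zero[k] <- d$zero; vectors[[k]] <- d$vector
      }
    }
  }
  sel <- if (n_out > 0L) sub_id else integer(0)
  out <- tibble::tibble(
    image_id = rep(fin$image_id, n_out),
    individual = rep(as.character(individual), n_out),
    sub_id = sub_id,
    start_kp = subs$start_kp[sel], end_kp = subs$end_kp[sel],
    start_pos = subs$start_pos[sel], end_pos = subs$end_pos[sel],
    p = subs$p[sel], direction = subs$direction[sel],
    dtype = dtype, sigma = sigma, zero = zero,
    vector = vectors)
  attr(out, "l_n") <- n_samples
  class(out) <- c("descriptor_set", class(out))
  out
}
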