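#' Synthetic fin populations
#'
#' Seeded generator of fin-shaped individuals. Each individual owns a
#' persistent shape signature: a smooth leading edge (bowed quadratic arc to
#' the apex), and a jagged trailing edge carrying a per-individual notch
#' sequence (5-12 notches with positions, depths and widths drawn once per
#' individual). The signature is fixed across all sightings; sightings vary
#' only by nuisance parameters. Pairwise signature distinctness is enforced
#' by redrawing individuals whose trailing-edge displacement profile lies
#' too close to an existing one.
#'
#' @param n_individuals population size.
#' @param seed RNG seed; the population is a pure function of it.
#' @param min_signature_dist minimum RMS distance between trailing-edge
#'   notch displacement profiles (unit-fin coordinates).
#' @return a tibble of class `fin_population`: one row per individual with
#'   shape parameters and a `notches` list-column (tibbles with `pos`,
#'   `depth`, `width`).
#' @export
make_population <- function(n_individuals, seed = 1L,
                            min_signature_dist = 0.004) {
  set.seed(seed)
  draw_individual <- function() {
    n_notch <- sample(5:12, 1L)
    n_micro <- 12L
    freq <- exp(stats::runif(n_micro, log(8), log(48)))
    list(apex_x = stats::runif(1, 0.32, 0.52),
         height = stats::runif(1, 0.85, 1.15),
         lead_curv = stats::runif(1, 0.10, 0.30),
         trail_curv = stats::runif(1, 0.04, 0.14),
         notches = tibble::tibble(
           pos = sort(stats::runif(n_notch, 0.08, 0.92)),
           depth = stats::rlnorm(n_notch, log(0.020), 0.45),
           width = stats::runif(n_notch, 0.012, 0.030)),
         # multi-scale edge roughness: individuality lives at every band of
         # the trailing edge, not only at notch width
         micro = tibble::tibble(
           freq = freq,
           amp = stats::runif(1, 0.02, 0.04) / freq^0.75,
           phase = stats::runif(n_micro, 0, 2 * pi)))
  }
  profile_of <- function(ind) {
    t <- seq(0, 1, length.out = 256L)
    nt <- ind$notches
    notch <- rowSums(vapply(seq_len(nrow(nt)), function(i) {
      nt$depth[i] * exp(-(t - nt$pos[i])^2 / (2 * nt$width[i]^2))
    }, numeric(256L)))
    notch + micro_displacement(ind$micro, t)
  }
  inds <- list(); profiles <- list()
  for (i in seq_len(n_individuals)) {
    for (try in seq_len(200L)) {
      cand <- draw_individual()
      prof <- profile_of(cand)
      ok <- all(vapply(profiles, function(q) {
        sqrt(mean((q - prof)^2)) >= min_signature_dist
      }, logical(1)))
      if (ok) break
    }
    if (!ok) stop("could not draw a distinct individual; lower ",
                  "min_signature_dist or the population size")
    inds[[i]] <- cand; profiles[[i]] <- prof
  }
  out <- tibble::tibble(
    individual = sprintf("ind%03d", seq_len(n_individuals)),
    apex_x = vapply(inds, `[[`, numeric(1), "apex_x"),
    height = vapply(inds, `[[`, numeric(1), "height"),
    lead_curv = vapply(inds, `[[`, numeric(1), "lead_curv"),
    trail_curv = vapply(inds, `[[`, numeric(1), "trail_curv"),
    notches = lapply(inds, `[[`, "notches"),
    micro = lapply(inds, `[[`, "micro"))
  class(out) <- c("fin_population", class(out))
  out
}

# fixed per-individual harmonic roughness along the trailing edge
micro_displacement <- function(micro, t) {
  rowSums(vapply(seq_len(nrow(micro)), function(i) {
    micro$amp[i] * sin(2 * pi * micro$freq[i] * t + micro$phase[i])
  }, numeric(length(t))))
}

# quadratic bezier sampled at n points
bezier2 <- function(a, c, b, n) {
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * a[1L] + 2 * (1 - t) * t * c[1L] + t^2 * b[1L],
        (1 - t)^2 * a[2L] + 2 * (1 - t) * t * c[2L] + t^2 * b[2L])
}

# unit-coordinate fin template (y up, base on [0,1] x {0}); returns points,
# the apex row index, and which samples belong to the trailing edge
fin_template <- function(ind, n_edge = 800L) {
  apex <- c(ind$apex_x, ind$height)
  # leading edge (0,0) -> apex, bowed forward (outward = -x side of chord)
  mid_l <- (c(0, 0) + apex) / 2
  nrm_l <- c(-apex[2L], apex[1L]); nrm_l <- nrm_l / sqrt(sum(nrm_l^2))
  lead <- bezier2(c(0, 0), mid_l - nrm_l * ind$lead_curv, apex, n_edge)
  # trailing edge apex -> (1,0), bowed backward, with notch displacements
  chord_t <- c(1, 0) - apex
  mid_t <- apex + chord_t / 2
  nrm_t <- c(-chord_t[2L], chord_t[1L]); nrm_t <- nrm_t / sqrt(sum(nrm_t^2))
  trail <- bezier2(apex, mid_t + nrm_t * ind$trail_curv, c(1, 0), n_edge)
  # notch displacement along local normals, cutting into the fin
  t <- seq(0, 1, length.out = n_edge)
  nt <- ind$notches
  disp <- rowSums(vapply(seq_len(nrow(nt)), function(i) {
    nt$depth[i] * exp(-(t - nt$pos[i])^2 / (2 * nt$width[i]^2))
  }, numeric(n_edge))) + micro_displacement(ind$micro, t)
  d <- rbind(trail[2L, ] - trail[1L, ], diff(trail))
  len <- sqrt(rowSums(d^2)); d <- d / ifelse(len > 0, len, 1)
  inward <- cbind(-d[, 2L], d[, 1L])   # left of travel points into the fin
  trail <- trail + inward * (-disp)
  pts <- rbind(lead, trail[-1L, , drop = FALSE])
  list(points = pts, apex_index = n_edge,
       trailing = c(rep(FALSE, n_edge - 1L), rep(TRUE, n_edge)))
}

#' Sighting nuisance presets
#'
#' Three difficulty regimes for synthetic sightings. `easy` keeps nuisances
#' mild (near-frontal, barely occluded); `standard` emulates routine survey
#' imagery (moderate rotation, scale and waterline occlusion, some splash);
#' `hard` pushes occlusion to the 75% cap and doubles the geometric
#' nuisances. All values are drawn per sighting from the preset's seeded
#' distributions.
#'
#' @param preset `"easy"`, `"standard"` or `"hard"`.
#' @return a named list of nuisance distribution parameters.
#' @export
sighting_preset <- function(preset = c("standard", "easy", "hard")) {
  preset <- match.arg(preset)
  switch(preset,
    easy = list(rot_max = 5, scale_rng = c(0.95, 1.05), shear_max = 0.02,
                bend_max = 0.005, jitter_sd = 0.1, occl_rng = c(0, 0.10),
                splash = 0),
    standard = list(rot_max = 20, scale_rng = c(0.80, 1.25),
                    shear_max = 0.08, bend_max = 0.015, jitter_sd = 0.15,
                    occl_rng = c(0, 0.45), splash = 0.0015),
    hard = list(rot_max = 40, scale_rng = c(0.60, 1.40), shear_max = 0.15,
                bend_max = 0.03, jitter_sd = 0.5, occl_rng = c(0, 0.75),
                splash = 0.003))
}

# draw one sighting spec from a preset (uses the current RNG stream)
draw_sighting <- function(pp) {
  list(rotation = stats::runif(1, -pp$rot_max, pp$rot_max) * pi / 180,
       scale = stats::runif(1, pp$scale_rng[1L], pp$scale_rng[2L]),
       shear = stats::runif(1, -pp$shear_max, pp$shear_max),
       bend = stats::runif(1, 0, pp$bend_max),
       jitter_sd = pp$jitter_sd,
       occlusion = stats::runif(1, pp$occl_rng[1L], pp$occl_rng[2L]),
       splash = pp$splash)
}

reference_sighting <- function() {
  list(rotation = 0, scale = 1, shear = 0, bend = 0, jitter_sd = 0,
       occlusion = 0, splash = 0)
}

#' Render one sighting of an individual
#'
#' Applies the sighting's nuisance transform (bend, out-of-plane shear
#' proxy, scale, in-plane rotation, contour jitter) to the individual's fin
#' template, places it on a canvas with the fin base at the waterline, and
#' crops it at the raised waterline implied by the occlusion fraction. The
#' fin is deliberately *not* a closed region of its own: the emitted
#' ground-truth hierarchy merges the above-water fin with the underwater
#' body silhouette into a single region, so only an open boundary arc traces
#' the fin — the situation the contour-stroke detector exists for.
#'
#' @param ind one row of a [make_population()] tibble (as a list or 1-row
#'   tibble).
#' @param sighting a sighting spec (see [sighting_preset()]), or `NULL` for
#'   the canonical reference view.
#' @param canvas `c(height, width)` in pixels.
#' @param render if `FALSE`, skip the raster image and hierarchy and return
#'   only the ground-truth contour and tip (fast path for
#'   identification-only studies).
#' @param seed per-sighting RNG seed (jitter, splash, distractors).
#' @return list with `contour` (open [planar_curve()], base-of-leading-edge
#'   to base-of-trailing-edge above the waterline), `tip` (arc fraction of
#'   the apex), `water_row`, and when rendered also `image` (h x w x 3
#'   array), `hierarchy` ([region_hierarchy()]), `fin_mask`.
#' @export
render_sighting <- function(ind, sighting = NULL, canvas = c(480L, 640L),
                            render = TRUE, seed = 1L, fin_px = 180) {
  if (is.data.frame(ind)) {
    ind <- list(individual = ind$individual[1L], apex_x = ind$apex_x[1L],
                height = ind$height[1L], lead_curv = ind$lead_curv[1L],
                trail_curv = ind$trail_curv[1L],
                notches = ind$notches[[1L]], micro = ind$micro[[1L]])
  }
  if (is.null(sighting)) sighting <- reference_sighting()
  set.seed(seed)
  h <- canvas[1L]; w <- canvas[2L]
  tmpl <- fin_template(ind)
  pts <- tmpl$points
  # bend: smooth lateral displacement growing with height
  pts[, 1L] <- pts[, 1L] + sighting$bend * sin(pi * pts[, 2L] /
                                                 max(ind$height, 1e-6))
  # out-of-plane shear proxy
  pts[, 1L] <- pts[, 1L] + sighting$shear * pts[, 2L]
  # place on canvas: base centred at (cx, water_base), y flipped to rows
  side <- fin_px * sighting$scale
  cx <- w / 2; base_row <- round(h * 0.62)
  px <- cbind(cx + (pts[, 1L] - 0.5) * side, base_row - pts[, 2L] * side)
  # in-plane rotation about the base centre
  ct <- cos(sighting$rotation); st <- sin(sighting$rotation)
  rel <- sweep(px, 2L, c(cx, base_row))
  px <- cbind(rel[, 1L] * ct - rel[, 2L] * st + cx,
              rel[, 1L] * st + rel[, 2L] * ct + base_row)
  # contour jitter (sensor noise / wet-edge shimmer), lightly re-smoothed
  if (sighting$jitter_sd > 0) {
    px <- px + matrix(stats::rnorm(length(px), 0, sighting$jitter_sd),
                      ncol = 2L)
    px <- gaussian_smooth(curve_unchecked(px), 1)$points
  }
  apex_i <- tmpl$apex_index
  # waterline crop: occlusion fraction of the fin's vertical extent
  top_row <- min(px[, 2L])
  water_row <- base_row - sighting$occlusion * (base_row - top_row)
  vis <- px[, 2L] <= water_row
  vis_run <- visible_run(vis, apex_i)
  contour_pts <- clip_to_water(px, vis_run, water_row)
  apex_xy <- contour_pts$points[contour_pts$apex_index, ]
  crv <- planar_curve(dedupe_consecutive(contour_pts$points), closed = FALSE)
  s <- arc_table(crv)
  apex_i2 <- which.min((crv$points[, 1L] - apex_xy[1L])^2 +
                         (crv$points[, 2L] - apex_xy[2L])^2)
  tip <- s[apex_i2] / s[length(s)]
  out <- list(contour = crv, tip = tip, water_row = water_row,
              individual = ind$individual, sighting = sighting)
  if (!render) return(out)

  fin_mask <- polygon_mask(rbind(contour_pts$points,
                                 contour_pts$points[1L, ]), h, w)
  # underwater body: wide half-ellipse under the waterline
  ys <- matrix(seq_len(h), h, w)
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  body <- ((xs - cx) / (1.6 * side))^2 +
    ((ys - (water_row + 0.25 * side)) / (0.45 * side))^2 <= 1
  # keep the body just proud of the waterline so fin and body form one
  # 8-connected region (the fin is never a closed region of its own)
  body <- body & ys > water_row - 2
  finbody <- fin_mask | body
  # distractor blobs in open water, away from the fin/body
  distract <- list()
  for (d in seq_len(2L)) {
    for (try in seq_len(20L)) {
      dc <- c(stats::runif(1, 0.12 * w, 0.88 * w),
              stats::runif(1, water_row + 8, h - 8))
      rr <- stats::runif(1, 12, 28)
      m <- (xs - dc[1L])^2 / rr^2 + (ys - dc[2L])^2 / (0.6 * rr)^2 <= 1
      if (!any(m & finbody) && sum(m) > 20) { distract[[d]] <- m; break }
    }
  }
  distract <- Filter(Negate(is.null), distract)
  above <- ys <= water_row
  background_sky <- above & !finbody
  background_water <- !above & !finbody &
    !Reduce(`|`, distract, matrix(FALSE, h, w))
  hier <- fixture_hierarchy(list(sky = background_sky,
                                 water = background_water,
                                 finbody = finbody),
                            distract, h, w)
  img <- render_scene(h, w, water_row, fin_mask, body, distract,
                      sighting$splash)
  out$image <- img
  out$hierarchy <- hier
  out$fin_mask <- fin_mask
  out
}

# longest contiguous visible run containing the apex
visible_run <- function(vis, apex_i) {
  if (!vis[apex_i]) stop("fin apex below the waterline: occlusion too severe")
  a <- apex_i
  while (a > 1L && vis[a - 1L]) a <- a - 1L
  b <- apex_i
  while (b < length(vis) && vis[b + 1L]) b <- b + 1L
  structure(c(a, b), apex_local = apex_i - a + 1L)
}

# clip the contour run to the waterline, interpolating exact crossings
clip_to_water <- function(px, run, water_row) {
  a <- run[1L]; b <- run[2L]
  pts <- px[a:b, , drop = FALSE]
  pre <- NULL; post <- NULL
  if (a > 1L) {
    p0 <- px[a - 1L, ]; p1 <- px[a, ]
    t <- (water_row - p0[2L]) / (p1[2L] - p0[2L])
    pre <- p0 + t * (p1 - p0)
  }
  if (b < nrow(px)) {
    p0 <- px[b, ]; p1 <- px[b + 1L, ]
    t <- (water_row - p0[2L]) / (p1[2L] - p0[2L])
    post <- p0 + t * (p1 - p0)
  }
  pts2 <- rbind(pre, pts, post)
  apex_local <- attr(run, "apex_local")
  list(points = pts2,
       apex_index = apex_local + (if (is.null(pre)) 0L else 1L))
}

dedupe_consecutive <- function(p, eps = 1e-9) {
  keep <- c(TRUE, rowSums(abs(diff(p))) > eps)
  p[keep, , drop = FALSE]
}

# even-odd scanline polygon fill (polygon given as closed point loop)
polygon_mask <- function(poly, h, w) {
  mask <- matrix(FALSE, h, w)
  n <- nrow(poly) - 1L
  x <- poly[, 1L]; y <- poly[, 2L]
  for (row in seq_len(h)) {
    yr <- row
    j <- n
    xs <- numeric(0)
    for (i in seq_len(n)) {
      if ((y[i] <= yr && y[j] > yr) || (y[j] <= yr && y[i] > yr)) {
        xs <- c(xs, x[i] + (yr - y[i]) / (y[j] - y[i]) * (x[j] - x[i]))
      }
      j <- i
    }
    if (length(xs) >= 2L) {
      xs <- sort(xs)
      for (k in seq(1L, length(xs) - 1L, by = 2L)) {
        c1 <- max(1L, ceiling(xs[k])); c2 <- min(w, floor(xs[k + 1L]))
        if (c1 <= c2) mask[row, c1:c2] <- TRUE
      }
    }
  }
  mask
}

# ground-truth merge tree over the leaf masks (levels fixed by design)
fixture_hierarchy <- function(bg_leaves, distract, h, w) {
  masks <- list(bg_leaves$sky, bg_leaves$water, bg_leaves$finbody)
  levels <- c(0, 0, 0)
  parent <- rep(NA_integer_, 3L)
  for (m in distract) { masks <- c(masks, list(m)); levels <- c(levels, 0) }
  parent <- rep(NA_integer_, length(masks))
  # water + distractors -> open-water node
  wnode <- length(masks) + 1L
  wmask <- bg_leaves$water
  for (m in distract) wmask <- wmask | m
  masks[[wnode]] <- wmask; levels[wnode] <- 0.30
  parent[c(2L, if (length(distract) > 0) 4L:(3L + length(distract)))] <- wnode
  parent <- c(parent, NA_integer_)
  # + sky -> background node
  bnode <- wnode + 1L
  masks[[bnode]] <- wmask | bg_leaves$sky; levels[bnode] <- 0.60
  parent[c(1L, wnode)] <- bnode
  parent <- c(parent, NA_integer_)
  # + fin/body -> root
  rnode <- bnode + 1L
  masks[[rnode]] <- matrix(TRUE, h, w); levels[rnode] <- 1
  parent[c(3L, bnode)] <- rnode
  parent <- c(parent, NA_integer_)
  region_hierarchy(masks, levels, parent)
}

# paint the scene: water, sky, fin/body, distractors, waterline, splash
render_scene <- function(h, w, water_row, fin_mask, body, distract, splash) {
  img <- array(0, c(h, w, 3L))
  ys <- matrix(seq_len(h), h, w)
  above <- ys <= water_row
  sky <- c(0.66, 0.73, 0.79); water <- c(0.33, 0.44, 0.54)
  fin <- c(0.12, 0.13, 0.15); rock <- c(0.47, 0.42, 0.38)
  for (c3 in 1:3) {
    layer <- ifelse(above, sky[c3], water[c3]) +
      matrix(stats::rnorm(h * w, 0, 0.015), h, w)
    layer[fin_mask] <- fin[c3] + stats::rnorm(sum(fin_mask), 0, 0.01)
    layer[body] <- 0.65 * water[c3] + 0.35 * fin[c3]
    for (m in distract) layer[m] <- rock[c3] + stats::rnorm(sum(m), 0, 0.01)
    wl <- abs(ys - water_row) < 1
    layer[wl & !fin_mask] <- pmin(layer[wl & !fin_mask] + 0.08, 1)
    img[, , c3] <- pmin(pmax(layer, 0), 1)
  }
  if (splash > 0) {
    band <- which(ys >= water_row - 5 & ys <= water_row + 7)
    n_spl <- stats::rbinom(1L, length(band), splash * 25)
    if (n_spl > 0) {
      at <- sample(band, n_spl)
      for (c3 in 1:3) {
        layer <- img[, , c3]; layer[at] <- 0.95; img[, , c3] <- layer
      }
    }
  }
  img
}

#' Generate a synthetic benchmark dataset
#'
#' One-shot split: the first sighting of every individual is the reference
#' (canonical, unoccluded view); the rest are queries drawn from the
#' nuisance preset. Everything is a pure function of `seed`, and the
#' manifest records every parameter.
#'
#' @param n_individuals population size.
#' @param sightings_per_individual sightings per individual (>= 2).
#' @param preset nuisance preset name, see [sighting_preset()].
#' @param seed master seed.
#' @param canvas canvas size `c(height, width)`.
#' @param fin_px rendered fin height scale in pixels.
#' @param render render images and hierarchy fixtures (`FALSE` keeps only
#'   contours and tips).
#' @return an object of class `synthetic_dataset`: list with `labels`
#'   (tibble: `image_id`, `individual`, `role`, `occlusion`), `contours`,
#'   `tips`, `images`, `hierarchies` (named lists; the latter two `NULL`
#'   when not rendered), `population`, `manifest`.
#' @export
make_dataset <- function(n_individuals, sightings_per_individual,
                         preset = "standard", seed = 1L,
                         canvas = c(480L, 640L), fin_px = 180,
                         render = FALSE) {
  stopifnot(sightings_per_individual >= 2L)
  pop <- make_population(n_individuals, seed = seed)
  pp <- sighting_preset(preset)
  labels <- list(); contours <- list(); tips <- list()
  images <- list(); hierarchies <- list()
  set.seed(seed + 1L)
  sighting_seeds <- sample.int(2^30, n_individuals * sightings_per_individual)
  k <- 0L
  for (i in seq_len(n_individuals)) {
    for (srep in seq_len(sightings_per_individual)) {
      k <- k + 1L
      role <- if (srep == 1L) "reference" else "query"
      set.seed(sighting_seeds[k])
      spec <- if (role == "reference") reference_sighting()
              else draw_sighting(pp)
      # queries must keep at least 25% of the trailing edge visible;
      # the 0.75 occlusion cap plus an explicit re-check enforce it
      id <- sprintf("%s_s%02d", pop$individual[i], srep)
      sg <- render_sighting(pop[i, ], spec, canvas = canvas,
                            render = render, seed = sighting_seeds[k],
                            fin_px = fin_px)
      labels[[k]] <- tibble::tibble(image_id = id,
                                    individual = pop$individual[i],
                                    role = role,
                                    occlusion = spec$occlusion)
      contours[[id]] <- sg$contour
      tips[[id]] <- sg$tip
      if (render) {
        images[[id]] <- sg$image
        hierarchies[[id]] <- sg$hierarchy
      }
    }
  }
  manifest <- list(n_individuals = n_individuals,
                   sightings_per_individual = sightings_per_individual,
                   preset = preset, preset_params = pp, seed = seed,
                   canvas = canvas, rendered = render)
  structure(list(labels = dplyr::bind_rows(labels),
                 contours = contours, tips = tips,
                 images = if (render) images else NULL,
                 hierarchies = if (render) hierarchies else NULL,
                 population = pop, manifest = manifest),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset: %d individuals, %d images (%s preset, seed %d)%s>\n",
    x$manifest$n_individuals, nrow(x$labels), x$manifest$preset,
    x$manifest$seed, if (x$manifest$rendered) ", rendered" else ""))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Images as PNG, contours as curve CSVs, labels as CSV, manifest as JSON,
#' hierarchies as labelled-mask PNG + JSON tree.
#'
#' @param dataset a [make_dataset()] object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE)
  tips <- tibble::tibble(image_id = names(dataset$tips),
                         tip = as.numeric(dataset$tips))
  utils::write.csv(tips, file.path(dir, "tips.csv"), row.names = FALSE)
  for (id in names(dataset$contours)) {
    write_curve_csv(dataset$contours[[id]],
                    file.path(dir, paste0(id, "_contour.csv")))
  }
  if (!is.null(dataset$images)) {
    for (id in names(dataset$images)) {
      png::writePNG(dataset$images[[id]], file.path(dir, paste0(id, ".png")))
      write_hierarchy(dataset$hierarchies[[id]],
                      file.path(dir, paste0(id, "_hier")))
    }
  }
  jsonlite::write_json(dataset$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Persist and restore region hierarchies
#'
#' A hierarchy whose leaves partition the image is stored as a labelled-mask
#' PNG (leaf index per pixel) plus a JSON table of `(id, level, parent)`
#' rows; any backend emitting this format can feed the adapter.
#'
#' @param h a [region_hierarchy()] whose leaf masks partition the image.
#' @param prefix path prefix; writes `<prefix>_labels.png` and
#'   `<prefix>_tree.json`.
#' @return `write_hierarchy` returns `prefix` invisibly; `read_hierarchy`
#'   the restored [region_hierarchy()].
#' @export
write_hierarchy <- function(h, prefix) {
  n <- length(h$masks)
  children <- lapply(seq_len(n), function(i) which(h$parent == i))
  leaves <- which(vapply(children, length, integer(1)) == 0L)
  if (length(leaves) > 255L) stop("more than 255 leaves: not representable")
  lab <- matrix(0L, h$dim[1L], h$dim[2L])
  for (li in seq_along(leaves)) lab[h$masks[[leaves[li]]]] <- li
  if (any(lab == 0L)) stop("hierarchy leaves do not partition the image")
  png::writePNG(lab / 255, paste0(prefix, "_labels.png"))
  tree <- list(leaves = leaves,
               levels = h$levels,
               parent = ifelse(is.na(h$parent), -1L, h$parent))
  jsonlite::write_json(tree, paste0(prefix, "_tree.json"), digits = NA)
  invisible(prefix)
}

#' @rdname write_hierarchy
#' @export
read_hierarchy <- function(prefix) {
  lab <- round(png::readPNG(paste0(prefix, "_labels.png")) * 255)
  tree <- jsonlite::read_json(paste0(prefix, "_tree.json"),
                              simplifyVector = TRUE)
  parent <- as.integer(tree$parent)
  parent[parent == -1L] <- NA_integer_
  n <- length(parent)
  leaves <- as.integer(tree$leaves)
  masks <- vector("list", n)
  for (li in seq_along(leaves)) masks[[leaves[li]]] <- lab == li
  # internal nodes: union of children, bottom-up by level order
  for (i in order(tree$levels)) {
    if (!is.null(masks[[i]])) next
    ch <- which(parent == i)
    m <- Reduce(`|`, masks[ch])
    masks[[i]] <- m
  }
  region_hierarchy(masks, tree$levels, parent)
}
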