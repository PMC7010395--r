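#' Pipeline configuration
#'
#' One flat record of every tunable in the pipeline, with the method's
#' canonical values as defaults. Unknown keys are rejected, and a config
#' round-trips losslessly through JSON.
#'
#' @param ... overrides of default entries (`name = value`).
#' @return a named list of class `fin_config`.
#' @export
fin_config <- function(...) {
  cfg <- list(
    # candidate generation
    boundary_samples = 128L, stroke_keypoints = 7L,
    stroke_sigma = 1, stroke_m = 4, regions_k = 12L, pool_size = 200L,
    min_area_frac = 0.001, dup_iou = 0.95,
    # stroke scoring
    dict_words = 20L, patch_sizes = c(16L, 24L, 32L, 40L), band = 4L,
    stride = 1L, nms_overlap = 0.2, nms_tol = 2,
    detect_threshold = 0.5, fmeasure_tol_frac = 0.0075,
    regressor_trees = 500L,
    # biometric encoding
    fin_samples = 1024L, fin_keypoints = 50L, fin_sigma = 2, fin_m = 8,
    sub_samples = 256L, scales = c(1, 2, 4, 8), dog_m = 2,
    types = c("dogn", "normal"),
    # fin space
    partitions_per_edge = 5L, scale_bins = 5L, tip_sigma = 16,
    classifier_trees = 500L, neg_ratio = 5,
    # synthetic data / misc
    canvas = c(480L, 640L), seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "fin_config")
}

#' @rdname fin_config
#' @param config a `fin_config`.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname fin_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  ints <- c("boundary_samples", "stroke_keypoints", "regions_k", "pool_size",
            "dict_words", "patch_sizes", "regressor_trees", "fin_samples",
            "fin_keypoints", "sub_samples", "partitions_per_edge",
            "scale_bins", "classifier_trees", "canvas", "seed", "stride")
  for (k in intersect(ints, names(raw))) raw[[k]] <- as.integer(raw[[k]])
  do.call(fin_config, raw)
}

#' Encode a synthetic dataset into descriptor sets
#'
#' Wraps [fin_contour()] + [encode_fin()] over the ground-truth contours of
#' a dataset. References are encoded in both directions, queries in one.
#'
#' @param dataset a [make_dataset()] object.
#' @param role `"reference"`, `"query"` or `"all"`.
#' @param types,scales,n_keypoints encoding parameters (see [encode_fin()]).
#' @param config optional [fin_config()] supplying `fin_samples` and
#'   `sub_samples`.
#' @return a `descriptor_set` tibble covering the selected images, with
#'   `individual` labels attached.
#' @export
encode_dataset <- function(dataset, role = "all",
                           types = c("dogn", "normal"),
                           scales = c(1, 2, 4, 8), n_keypoints = 50L,
                           config = fin_config()) {
  lab <- dataset$labels
  if (role != "all") lab <- lab[lab$role == role, , drop = FALSE]
  sets <- vector("list", nrow(lab))
  for (i in seq_len(nrow(lab))) {
    id <- lab$image_id[i]
    fin <- fin_contour(dataset$contours[[id]], image_id = id,
                       n_samples = config$fin_samples)
    sets[[i]] <- encode_fin(
      fin, scales = scales, types = types,
      both_directions = lab$role[i] == "reference",
      n_keypoints = n_keypoints, n_samples = config$sub_samples,
      individual = lab$individual[i])
  }
  out <- dplyr::bind_rows(sets)
  attr(out, "l_n") <- config$sub_samples
  class(out) <- c("descriptor_set", class(out))
  out
}

# per-stratum LNBNN class sums for a set of queries: tibble
# (query_id, stratum, class, score); computing once lets single-scale and
# multi-scale rankings be assembled without repeating the NN searches
lnbnn_scores_by_stratum <- function(queries, catalog) {
  queries <- dplyr::filter(queries, !.data$zero)
  out <- list()
  for (qid in unique(queries$image_id)) {
    q <- queries[queries$image_id == qid, , drop = FALSE]
    key <- paste(q$dtype, q$sigma, sep = "_")
    for (k in unique(key)) {
      stratum <- catalog$strata[[k]]
      if (is.null(stratum)) next
      qmat <- do.call(rbind, q$vector[key == k])
      sc <- stratum_scores(qmat, stratum, catalog$classes)
      out[[length(out) + 1L]] <- tibble::tibble(
        query_id = qid, stratum = k, class = catalog$classes,
        score = colSums(sc$f))
    }
  }
  dplyr::bind_rows(out)
}

# combine per-stratum scores into ranked predictions (weights default 1)
combine_stratum_scores <- function(stratum_scores, strata = NULL,
                                   weights = NULL) {
  df <- stratum_scores
  if (!is.null(strata)) df <- df[df$stratum %in% strata, , drop = FALSE]
  if (!is.null(weights)) {
    df$score <- df$score * weights[df$stratum]
  }
  df |>
    dplyr::group_by(.data$query_id, .data$class) |>
    dplyr::summarise(score = sum(.data$score), .groups = "drop_last") |>
    dplyr::arrange(dplyr::desc(.data$score), .data$class,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Identify queries against a catalog
#'
#' The `lnbnn` mode ranks individuals by the multi-scale LNBNN score
#' (equal stratum weights); the `finspace` mode additionally requires a
#' binning and a trained match classifier and ranks by match probability.
#'
#' @param queries a `descriptor_set` of query images.
#' @param catalog a [build_catalog()] object.
#' @param mode `"lnbnn"` or `"finspace"`.
#' @param model a [train_match_classifier()] fit (finspace mode).
#' @param binning a [fin_space_binning()] (finspace mode).
#' @return predictions tibble: `query_id`, `class`, `score`, `rank`.
#' @export
identify_queries <- function(queries, catalog, mode = c("lnbnn", "finspace"),
                             model = NULL, binning = NULL) {
  mode <- match.arg(mode)
  if (mode == "lnbnn") {
    return(combine_stratum_scores(lnbnn_scores_by_stratum(queries, catalog)))
  }
  if (is.null(model) || is.null(binning)) {
    stop("finspace mode needs a match classifier and a binning")
  }
  out <- list()
  for (qid in unique(queries$image_id)) {
    q <- queries[queries$image_id == qid, , drop = FALSE]
    pred <- classify_finspace(q, catalog, model, binning)
    pred$query_id <- qid
    out[[length(out) + 1L]] <- pred
  }
  dplyr::bind_rows(out)
}

#' Assemble fin-space scoring rows for classifier training
#'
#' Builds, for every (query, class) pair, the 550-bin scoring vector and
#' the binary same-individual label.
#'
#' @param queries a `descriptor_set` of query images with `individual`
#'   truth labels.
#' @param catalog a bin-annotated catalog (`drop_unbinned = TRUE`).
#' @param binning the [fin_space_binning()].
#' @return tibble: `query_id`, `individual`, `class`, `label`, `vector`
#'   (list of scoring vectors).
#' @export
scoring_rows <- function(queries, catalog, binning) {
  out <- list()
  for (qid in unique(queries$image_id)) {
    q <- queries[queries$image_id == qid, , drop = FALSE]
    m <- scoring_matrix(q, catalog, binning)
    out[[length(out) + 1L]] <- tibble::tibble(
      query_id = qid,
      individual = q$individual[1L],
      class = catalog$classes,
      label = catalog$classes == q$individual[1L],
      vector = lapply(seq_len(nrow(m)), function(i) m[i, ]))
  }
  dplyr::bind_rows(out)
}

#' Detect fin candidates in one image
#'
#' Region hierarchy (supplied fixture or built by the fallback backend),
#' region selection, stroke-candidate generation, and optionally feature
#' extraction + quality regression + non-maximum suppression when a trained
#' detector is supplied.
#'
#' @param image RGB array or grayscale matrix.
#' @param hierarchy optional precomputed [region_hierarchy()] fixture.
#' @param detector optional list with `dict` ([train_visual_dictionary()])
#'   and `regressor` ([train_quality_regressor()]).
#' @param config a [fin_config()].
#' @return a `stroke_set` tibble; with a detector, scored (`score` column),
#'   NMS-filtered and thresholded at `config$detect_threshold`.
#' @export
detect_fins <- function(image, hierarchy = NULL, detector = NULL,
                        config = fin_config()) {
  h <- if (is.null(hierarchy)) build_hierarchy(image) else hierarchy
  pool <- select_regions(h, pool_size = config$pool_size,
                         k = config$regions_k,
                         min_area_frac = config$min_area_frac,
                         dup_iou = config$dup_iou)
  strokes <- generate_stroke_candidates(
    pool, n_keypoints = config$stroke_keypoints,
    resample_n = config$boundary_samples,
    sigma = config$stroke_sigma, m = config$stroke_m)
  if (is.null(detector) || nrow(strokes) == 0L) return(strokes)
  feats <- stroke_features(image, strokes, detector$dict,
                           band = config$band, stride = config$stride)
  strokes$score <- score_strokes(detector$regressor, feats)
  kept <- stroke_nms(strokes, overlap_thresh = config$nms_overlap,
                     tol = config$nms_tol)
  kept[kept$score >= config$detect_threshold, , drop = FALSE]
}

#' Ground-truth quality of stroke candidates
#'
#' Computes the boundary-matching F-measure of each stroke against a truth
#' contour, using a cheap upper bound (distance-to-truth counts) to skip
#' the exact bipartite matching where it cannot beat the current best.
#'
#' @param strokes a `stroke_set`.
#' @param truth the ground-truth fin contour ([planar_curve()]).
#' @param tol match tolerance in pixels.
#' @param exact compute the exact F for every stroke (`TRUE`) or only where
#'   the upper bound allows an improvement over the running best (`FALSE`,
#'   returns exact values for winners and upper bounds elsewhere, which is
#'   sufficient for achievable-quality analyses).
#' @return numeric vector of qualities (exact, or upper-bounded when
#'   `exact = FALSE`), with attribute `"best"` = exact best quality.
#' @export
stroke_ground_quality <- function(strokes, truth, tol = 2, exact = TRUE) {
  tpix <- rasterise_curve(truth)
  n <- nrow(strokes)
  if (n == 0L) return(structure(numeric(0), best = 0))
  pix <- lapply(strokes$path, rasterise_curve)
  # distance map to the truth pixels on a padded grid gives an O(1) lookup
  # for "candidate pixel near truth" counts (the F upper bound)
  pad <- ceiling(tol) + 2L
  all_xy <- do.call(rbind, c(pix, list(tpix)))
  x0 <- min(all_xy[, 1L]) - pad; y0 <- min(all_xy[, 2L]) - pad
  wd <- max(all_xy[, 1L]) + pad - x0 + 1L
  ht <- max(all_xy[, 2L]) + pad - y0 + 1L
  grid <- matrix(1, ht, wd)
  grid[cbind(tpix[, 2L] - y0 + 1L, tpix[, 1L] - x0 + 1L)] <- 0
  dmap <- matrix(EBImage::distmap(grid), ht, wd)
  ub <- numeric(n)
  for (i in seq_len(n)) {
    a <- pix[[i]]
    near <- sum(dmap[cbind(a[, 2L] - y0 + 1L, a[, 1L] - x0 + 1L)] <= tol)
    p_ub <- near / nrow(a)
    r_ub <- min(near, nrow(tpix)) / nrow(tpix)
    ub[i] <- if (p_ub + r_ub > 0) 2 * p_ub * r_ub / (p_ub + r_ub) else 0
  }
  vals <- ub
  best <- 0
  for (i in order(-ub)) {
    if (!exact && ub[i] <= best) break
    f <- contour_fmeasure(pix[[i]], tpix, tol)$f
    vals[i] <- f
    best <- max(best, f)
  }
  structure(vals, best = best)
}

#' Evaluate identification predictions from files or tibbles
#'
#' Thin wrapper around [evaluate_identification()] accepting CSV paths.
#' @param predictions tibble or CSV path (`query_id`, `class`, `score`).
#' @param truth tibble or CSV path (`image_id`/`query_id`, `individual`).
#' @return an `identification_evaluation`.
#' @export
fin_evaluate <- function(predictions, truth) {
  if (is.character(predictions)) {
    predictions <- tibble::as_tibble(utils::read.csv(predictions))
  }
  if (is.character(truth)) truth <- tibble::as_tibble(utils::read.csv(truth))
  if ("image_id" %in% names(truth) && !"query_id" %in% names(truth)) {
    truth <- dplyr::rename(truth, query_id = "image_id")
  }
  evaluate_identification(predictions, truth[, c("query_id", "individual")])
}

#' Run the standard synthetic identification benchmark
#'
#' Generates a seeded dataset, encodes references (both directions) and
#' queries (one direction), and evaluates the multi-scale LNBNN baseline;
#' optionally the per-scale baselines and the fin-space classifier.
#' Descriptor sets are encoded from ground-truth contours, isolating
#' identification performance from detection.
#'
#' @param n_individuals,sightings_per_individual,preset,seed passed to
#'   [make_dataset()].
#' @param types descriptor types to encode.
#' @param scales filter scales.
#' @param n_keypoints fin keypoints bounding subsections (the benchmark
#'   default 12 keeps the descriptor count desk-scale).
#' @param per_scale also evaluate each DoG-norm scale alone?
#' @param finspace also train/evaluate the fin-space match classifier
#'   (two-fold by individual, held-out probabilities)?
#' @param classifier_trees forest size for the match classifier.
#' @return list with the dataset labels, `lnbnn` evaluation, optional
#'   `per_scale` tibble and `finspace` evaluation.
#' @export
run_identification_benchmark <- function(n_individuals = 20L,
                                         sightings_per_individual = 6L,
                                         preset = "easy", seed = 1L,
                                         types = "dogn",
                                         scales = c(1, 2, 4, 8),
                                         n_keypoints = 12L,
                                         per_scale = FALSE,
                                         finspace = FALSE,
                                         classifier_trees = 300L) {
  ds <- make_dataset(n_individuals, sightings_per_individual,
                     preset = preset, seed = seed, render = FALSE)
  refs <- encode_dataset(ds, "reference", types = types, scales = scales,
                         n_keypoints = n_keypoints)
  queries <- encode_dataset(ds, "query", types = types, scales = scales,
                            n_keypoints = n_keypoints)
  truth <- ds$labels[ds$labels$role == "query",
                     c("image_id", "individual")]
  names(truth) <- c("query_id", "individual")
  catalog <- build_catalog(refs)
  per_stratum <- lnbnn_scores_by_stratum(queries, catalog)
  dog_strata <- grep("^dogn_", unique(per_stratum$stratum), value = TRUE)
  lnbnn_pred <- combine_stratum_scores(per_stratum, strata = dog_strata)
  out <- list(labels = ds$labels,
              lnbnn = evaluate_identification(lnbnn_pred, truth))
  if (per_scale) {
    out$per_scale <- dplyr::bind_rows(lapply(dog_strata, function(k) {
      ev <- evaluate_identification(
        combine_stratum_scores(per_stratum, strata = k), truth)
      tibble::tibble(stratum = k, ap = ev$ap, map = ev$map, top1 = ev$top1)
    }))
  }
  if (finspace) {
    binning <- fin_space_binning(sigma_set = scales,
                                 l_n = attr(refs, "l_n"),
                                 min_p = 2 / 1024)
    ref_lab <- ds$labels[ds$labels$role == "reference", , drop = FALSE]
    binned <- dplyr::bind_rows(lapply(seq_len(nrow(ref_lab)), function(i) {
      id <- ref_lab$image_id[i]
      assign_bin(refs[refs$image_id == id, , drop = FALSE], binning,
                 tip = ds$tips[[id]])
    }))
    fcat <- build_catalog(binned, drop_unbinned = TRUE)
    rows <- scoring_rows(queries, fcat, binning)
    model <- train_match_classifier(rows, ntree = classifier_trees,
                                    seed = seed)
    fs_pred <- dplyr::rename(model$cv[, c("query_id", "class", "prob")],
                             score = "prob")
    out$finspace <- evaluate_identification(fs_pred, truth)
    out$finspace_model <- model
    # LNBNN over the same binned catalog (dual descriptor types), for a
    # like-for-like comparison with the fin-space classifier
    base_pred <- combine_stratum_scores(
      lnbnn_scores_by_stratum(queries, fcat))
    out$lnbnn_binned <- evaluate_identification(base_pred, truth)
  }
  out
}

#' Run the synthetic detection benchmark
#'
#' Renders `n_images` standard-preset sightings with ground-truth hierarchy
#' fixtures, generates stroke candidates from the fixtures, measures the
#' achievable quality (best ground-truth F-measure in the candidate pool)
#' per image, and evaluates detection with an oracle scorer (predicted
#' quality = ground-truth quality).
#'
#' @param n_images number of rendered sightings.
#' @param seed master seed.
#' @param preset nuisance preset.
#' @param thresholds quality-threshold grid for the PR surface.
#' @param config a [fin_config()].
#' @return list with `per_image` (tibble: `image_id`, `n_candidates`,
#'   `achievable`), `oracle_eval` (a `detection_evaluation`), `frac_high`
#'   (fraction of fins with a candidate of quality >= 0.9).
#' @export
run_detection_benchmark <- function(n_images = 50L, seed = 1L,
                                    preset = "standard",
                                    thresholds = seq(0.5, 0.9, by = 0.1),
                                    config = fin_config()) {
  pop <- make_population(max(10L, ceiling(n_images / 3L)), seed = seed)
  pp <- sighting_preset(preset)
  set.seed(seed + 1L)
  seeds <- sample.int(2^30, n_images)
  per <- list(); dets <- list()
  diag_tol <- config$fmeasure_tol_frac *
    sqrt(sum(as.numeric(config$canvas)^2))
  for (i in seq_len(n_images)) {
    set.seed(seeds[i])
    ind <- pop[((i - 1L) %% nrow(pop)) + 1L, ]
    sg <- render_sighting(ind, draw_sighting(pp), canvas = config$canvas,
                          render = TRUE, seed = seeds[i])
    pool <- select_regions(sg$hierarchy, pool_size = config$pool_size,
                           k = config$regions_k,
                           min_area_frac = config$min_area_frac,
                           dup_iou = config$dup_iou)
    strokes <- generate_stroke_candidates(
      pool, n_keypoints = config$stroke_keypoints,
      resample_n = config$boundary_samples,
      sigma = config$stroke_sigma, m = config$stroke_m)
    q <- stroke_ground_quality(strokes, sg$contour, tol = diag_tol,
                               exact = FALSE)
    best <- attr(q, "best")
    per[[i]] <- tibble::tibble(image_id = sprintf("img%03d", i),
                               n_candidates = nrow(strokes),
                               achievable = best)
    # oracle detector: the truth contour recovered perfectly and scored by
    # its own (computed) ground-truth quality
    f_self <- contour_fmeasure(sg$contour, sg$contour, tol = diag_tol)$f
    dets[[i]] <- tibble::tibble(image_id = sprintf("img%03d", i),
                                f_pred = f_self, f_ground = f_self)
  }
  per <- dplyr::bind_rows(per)
  dets <- dplyr::bind_rows(dets)
  truths <- tibble::tibble(image_id = per$image_id)
  list(per_image = per,
       oracle_eval = evaluate_detection(dets, truths, thresholds),
       frac_high = mean(per$achievable >= 0.9))
}
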