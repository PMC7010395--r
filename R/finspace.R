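#' Locate the fin tip along a fin contour
#'
#' The tip separates the (smooth) leading edge from the (jagged) trailing
#' edge and anchors the fin-space partitions. By default it is taken as the
#' vertex of maximal coarse-scale corner response (sigma = 16, m = 2 on the
#' 1024-vertex contour) — the fin apex is the dominant coarse curvature
#' event. Ground truth (e.g. from the synthetic generator) can override it.
#'
#' @param fin a [fin_contour()].
#' @param sigma,m coarse corner-response parameters.
#' @param override if non-`NULL`, returned as-is (arc-length fraction).
#' @return the tip position as an arc-length fraction in (0, 1).
#' @export
locate_tip <- function(fin, sigma = 16, m = 2, override = NULL) {
  if (!is.null(override)) return(as.numeric(override))
  resp <- dog_response(fin$path, sigma, m)
  s <- arc_table(fin$path)
  i <- which.max(resp$values)
  s[i] / s[length(s)]
}

#' Enumerate the spatial bins of fin space
#'
#' The leading and trailing edges are each divided into `n_per_edge` equal
#' arc-length partitions, giving 2 * n_per_edge ordered partitions along the
#' contour. Every connected (contiguous) combination of partitions is a
#' spatial bin: p(p+1)/2 bins for p partitions, i.e. 55 for the default 5
#' per edge.
#'
#' @param n_per_edge partitions per edge.
#' @return a tibble with `spatial_bin`, `first_part`, `last_part`,
#'   `n_parts`.
#' @export
enumerate_spatial_bins <- function(n_per_edge = 5L) {
  p <- 2L * as.integer(n_per_edge)
  grid <- expand.grid(first_part = seq_len(p), last_part = seq_len(p))
  grid <- grid[grid$first_part <= grid$last_part, ]
  grid <- grid[order(grid$first_part, grid$last_part), ]
  tibble::tibble(spatial_bin = seq_len(nrow(grid)),
                 first_part = grid$first_part,
                 last_part = grid$last_part,
                 n_parts = grid$last_part - grid$first_part + 1L)
}

#' Fin-space binning definition
#'
#' Fixes the discretisation of fin space: descriptor types, spatial bins
#' (connected partition runs), and filter-scale bins over the global scale
#' sigma_g = sigma / l_n * p (filter scale as a proportion of fin contour
#' length). Scale-bin edges default to logarithmically spaced half-open
#' intervals spanning the attainable sigma_g range for the configured
#' descriptor scales and subsection lengths.
#'
#' @param n_per_edge spatial partitions per edge.
#' @param dtypes descriptor types indexed by the space.
#' @param scale_edges increasing vector of scale-bin edges (length
#'   `n_scale_bins + 1`); `NULL` for the log-spaced default.
#' @param n_scale_bins number of filter-scale bins.
#' @param sigma_set descriptor filter scales in use.
#' @param l_n subsection sample count.
#' @param min_p smallest representable subsection length fraction (used for
#'   the default lower edge).
#' @return an object of class `fin_space_binning`; `n_bins(binning)` gives
#'   the total bin count (2 x 55 x 5 = 550 by default).
#' @export
fin_space_binning <- function(n_per_edge = 5L,
                              dtypes = c("dogn", "normal"),
                              scale_edges = NULL, n_scale_bins = 5L,
                              sigma_set = c(1, 2, 4, 8), l_n = 256L,
                              min_p = 2 / 1024) {
  spatial <- enumerate_spatial_bins(n_per_edge)
  if (is.null(scale_edges)) {
    lo <- min(sigma_set) / l_n * min_p
    hi <- max(sigma_set) / l_n * 1
    scale_edges <- exp(seq(log(lo), log(hi), length.out = n_scale_bins + 1L))
  }
  if (length(scale_edges) != n_scale_bins + 1L) {
    stop("scale_edges must have n_scale_bins + 1 entries")
  }
  structure(list(n_per_edge = as.integer(n_per_edge),
                 n_parts = 2L * as.integer(n_per_edge),
                 spatial = spatial,
                 dtypes = dtypes,
                 scale_edges = as.numeric(scale_edges),
                 n_scale_bins = as.integer(n_scale_bins),
                 l_n = as.integer(l_n)),
            class = "fin_space_binning")
}

#' @rdname fin_space_binning
#' @param binning a `fin_space_binning`.
#' @export
n_bins <- function(binning) {
  length(binning$dtypes) * nrow(binning$spatial) * binning$n_scale_bins
}

#' @export
print.fin_space_binning <- function(x, ...) {
  cat(sprintf(
    "<fin_space_binning: %d types x %d spatial x %d scale = %d bins>\n",
    length(x$dtypes), nrow(x$spatial), x$n_scale_bins, n_bins(x)))
  invisible(x)
}

#' Assign descriptors to fin-space bins
#'
#' A subsection occupies a partition when its arc interval covers strictly
#' more than half of that partition; the occupied set is a contiguous run by
#' construction and selects the spatial bin. The global filter scale
#' sigma_g = sigma / l_n * p selects the scale bin (half-open intervals,
#' clamped at the configured range ends). Descriptors occupying no
#' partition are unbinned (`NA`) and are excluded from fin-space matching.
#'
#' @param descs a `descriptor_set` tibble (needs `start_pos`, `end_pos`,
#'   `p`, `dtype`, `sigma`).
#' @param binning a [fin_space_binning()].
#' @param tip tip position of the descriptors' fin (arc fraction).
#' @return `descs` with an integer `bin` column (index into the flattened
#'   bin set, `NA` when unbinned) plus `spatial_bin` and `scale_bin`
#'   columns.
#' @export
assign_bin <- function(descs, binning, tip) {
  np <- binning$n_parts
  half <- binning$n_per_edge
  # partition boundaries along the contour: tip splits leading/trailing
  lead <- seq(0, tip, length.out = half + 1L)
  trail <- seq(tip, 1, length.out = half + 1L)
  starts <- c(lead[-length(lead)], trail[-length(trail)])
  ends <- c(lead[-1L], trail[-1L])
  run_key <- paste(binning$spatial$first_part, binning$spatial$last_part)
  spatial_of <- function(a, b) {
    ov <- pmin(b, ends) - pmax(a, starts)
    occ <- which(ov > (ends - starts) / 2)
    if (length(occ) == 0L) return(NA_integer_)
    binning$spatial$spatial_bin[match(paste(min(occ), max(occ)), run_key)]
  }
  sp <- mapply(spatial_of, descs$start_pos, descs$end_pos)
  sigma_g <- descs$sigma / binning$l_n * descs$p
  sc <- findInterval(sigma_g, binning$scale_edges, left.open = TRUE)
  sc <- pmin(pmax(sc, 1L), binning$n_scale_bins)   # clamp range ends
  dt <- match(descs$dtype, binning$dtypes)
  ns <- nrow(binning$spatial)
  bin <- (dt - 1L) * ns * binning$n_scale_bins +
    (sp - 1L) * binning$n_scale_bins + sc
  descs$spatial_bin <- as.integer(sp)
  descs$scale_bin <- as.integer(sc)
  descs$bin <- as.integer(bin)
  descs
}

#' Fin-space scoring vector for one query-class comparison
#'
#' Computes the LNBNN local match score of every query descriptor against
#' class `class` and, instead of collapsing them to a scalar, sum-pools the
#' scores over the fin-space bins of the *matched reference* descriptors.
#' With unit scale weights the vector's sum equals the plain LNBNN class
#' score over the same (binned) catalog — fin space rearranges the
#' evidence, it does not change its total.
#'
#' @param query a `descriptor_set` for one query image.
#' @param class a class (individual) label in the catalog.
#' @param catalog a [build_catalog()] built with `drop_unbinned = TRUE`
#'   from bin-annotated references.
#' @param binning the [fin_space_binning()] used for the references.
#' @return numeric vector of length `n_bins(binning)`.
#' @export
build_scoring_vector <- function(query, class, catalog, binning) {
  m <- scoring_matrix(query, catalog, binning)
  m[match(class, catalog$classes), ]
}

#' All query-class scoring vectors at once
#'
#' @inheritParams build_scoring_vector
#' @return matrix of dimension `length(catalog$classes)` x
#'   `n_bins(binning)`, rows ordered as `catalog$classes`.
#' @export
scoring_matrix <- function(query, catalog, binning) {
  nb <- n_bins(binning)
  nc <- length(catalog$classes)
  out <- matrix(0, nc, nb)
  query <- dplyr::filter(query, !.data$zero)
  if (nrow(query) == 0L) return(out)
  key <- paste(query$dtype, query$sigma, sep = "_")
  for (k in unique(key)) {
    stratum <- catalog$strata[[k]]
    if (is.null(stratum)) next
    if (anyNA(stratum$bin)) {
      stop("catalog stratum ", k, " has unbinned references; build the ",
           "catalog with drop_unbinned = TRUE")
    }
    qmat <- do.call(rbind, query$vector[key == k])
    sc <- stratum_scores(qmat, stratum, catalog$classes)
    for (ci in seq_len(nc)) {
      f <- sc$f[, ci]
      hit <- f > 0
      if (!any(hit)) next
      bins <- stratum$bin[sc$ref[hit, ci]]
      acc <- vapply(split(f[hit], bins), sum, numeric(1))
      idx <- as.integer(names(acc))
      out[ci, idx] <- out[ci, idx] + acc
    }
  }
  out
}

#' Train the fin-space match classifier
#'
#' Learns a random forest mapping query-class scoring vectors to the
#' probability that the query shows that class's individual. Cross-validated
#' two-fold *by individual* (the folds partition individuals, never queries,
#' so nothing learned about one individual leaks into its own evaluation);
#' the deployed model is refit on all rows. Class imbalance is handled by
#' down-sampling negative (non-matching) pairs to `neg_ratio` per positive,
#' seeded.
#'
#' @param scoring tibble with `query_id`, `individual` (query truth),
#'   `class` (catalog class compared against), `label` (logical,
#'   `class == individual`) and a `vector` list-column of scoring vectors.
#' @param ntree trees per forest.
#' @param neg_ratio negatives kept per positive during training.
#' @param seed RNG seed (folds, down-sampling, forests).
#' @return an object of class `match_classifier`: list with `forest`
#'   (deployment model), `cv` (tibble of held-out probabilities per row),
#'   `folds` (tibble individual/fold), `seed`, `ntree`.
#' @export
train_match_classifier <- function(scoring, ntree = 500L, neg_ratio = 5,
                                   seed = 1L) {
  inds <- sort(unique(scoring$individual))
  if (length(inds) < 4L) stop("need at least 4 individuals for two folds")
  set.seed(seed)
  shuffled <- sample(inds)
  fold_of <- stats::setNames(rep(1:2, length.out = length(inds)), shuffled)
  if (min(table(fold_of)) < 2L) stop("a fold has fewer than 2 individuals")
  folds <- tibble::tibble(individual = names(fold_of),
                          fold = as.integer(fold_of))
  x <- do.call(rbind, scoring$vector)
  y <- factor(ifelse(scoring$label, "same", "diff"),
              levels = c("diff", "same"))
  row_fold <- folds$fold[match(scoring$individual, folds$individual)]
  fit_fold <- function(train_rows) {
    pos <- train_rows[y[train_rows] == "same"]
    neg <- train_rows[y[train_rows] == "diff"]
    keep_n <- min(length(neg), ceiling(neg_ratio * max(length(pos), 1L)))
    neg <- sort(sample(neg, keep_n))
    rows <- sort(c(pos, neg))
    randomForest::randomForest(x = x[rows, , drop = FALSE], y = y[rows],
                               ntree = ntree)
  }
  cv_prob <- rep(NA_real_, nrow(scoring))
  for (f in 1:2) {
    set.seed(seed + f)
    model <- fit_fold(which(row_fold != f))
    test <- which(row_fold == f)
    cv_prob[test] <- stats::predict(model, x[test, , drop = FALSE],
                                    type = "prob")[, "same"]
  }
  set.seed(seed + 10L)
  final <- fit_fold(seq_len(nrow(scoring)))
  cv <- tibble::tibble(query_id = scoring$query_id,
                       individual = scoring$individual,
                       class = scoring$class,
                       fold = row_fold,
                       label = scoring$label,
                       prob = cv_prob)
  structure(list(forest = final, cv = cv, folds = folds, seed = seed,
                 ntree = ntree),
            class = "match_classifier")
}

#' @export
print.match_classifier <- function(x, ...) {
  cat(sprintf("<match_classifier: %d trees, %d individuals in 2 folds>\n",
              x$ntree, nrow(x$folds)))
  invisible(x)
}

#' @export
glance.match_classifier <- function(x, ...) {
  tibble::tibble(ntree = x$ntree,
                 n_pairs = nrow(x$cv),
                 n_individuals = nrow(x$folds),
                 cv_ap = average_precision(x$cv$prob, x$cv$label))
}

#' @export
tidy.match_classifier <- function(x, ...) {
  x$cv
}

#' Classify a query through fin space
#'
#' Builds the query's scoring vector against every catalog class and ranks
#' classes by the match classifier's probability of "query-is-same-class".
#' Ties (e.g. a degenerate constant model) are broken by class id, keeping
#' the ranking stable.
#'
#' @param query a `descriptor_set` for one query image.
#' @param catalog a bin-annotated [build_catalog()] (`drop_unbinned =
#'   TRUE`).
#' @param model a [train_match_classifier()] fit.
#' @param binning the [fin_space_binning()].
#' @return a `ranked_prediction` tibble (`class`, `score`, `rank`) where
#'   `score` is the match probability.
#' @export
classify_finspace <- function(query, catalog, model, binning) {
  m <- scoring_matrix(query, catalog, binning)
  prob <- stats::predict(model$forest, m, type = "prob")[, "same"]
  out <- tibble::tibble(class = catalog$classes, score = as.numeric(prob))
  out <- out[order(-out$score, out$class), ]
  out$rank <- seq_len(nrow(out))
  attr(out, "query_id") <- if (nrow(query) > 0L) query$image_id[1L]
                           else NA_character_
  class(out) <- c("ranked_prediction", class(out))
  out
}

#' Per-bin distinctiveness of fin space
#'
#' Quantifies how much individual identity each fin-space bin carries:
#' every query descriptor casts LNBNN scores over all classes, the
#' (descriptor, class) scores are grouped by the *query* descriptor's bin,
#' and a subsection-level identification AP is computed per bin. Empty bins
#' are flagged with `NA`.
#'
#' @param catalog a [build_catalog()] object.
#' @param queries a bin-annotated `descriptor_set` covering one or more
#'   query images (needs `individual` truth labels and `bin`).
#' @param binning the [fin_space_binning()].
#' @return a tibble with `bin`, `dtype`, `spatial_bin`, `scale_bin`,
#'   `n_descriptors`, `ap`.
#' @export
measure_bin_distinctiveness <- function(catalog, queries, binning) {
  queries <- dplyr::filter(queries, !.data$zero, !is.na(.data$bin))
  nb <- n_bins(binning)
  ns <- nrow(binning$spatial)
  acc_scores <- vector("list", nb)
  acc_labels <- vector("list", nb)
  key <- paste(queries$dtype, queries$sigma, sep = "_")
  for (k in unique(key)) {
    stratum <- catalog$strata[[k]]
    if (is.null(stratum)) next
    rows <- which(key == k)
    qmat <- do.call(rbind, queries$vector[rows])
    sc <- stratum_scores(qmat, stratum, catalog$classes)
    lab <- outer(queries$individual[rows], catalog$classes, "==")
    for (i in seq_along(rows)) {
      b <- queries$bin[rows[i]]
      acc_scores[[b]] <- c(acc_scores[[b]], sc$f[i, ])
      acc_labels[[b]] <- c(acc_labels[[b]], lab[i, ])
    }
  }
  ap <- vapply(seq_len(nb), function(b) {
    if (is.null(acc_scores[[b]])) return(NA_real_)
    average_precision(acc_scores[[b]], acc_labels[[b]])
  }, numeric(1))
  n_desc <- vapply(seq_len(nb), function(b) {
    length(acc_labels[[b]]) %/% max(length(catalog$classes), 1L)
  }, numeric(1))
  sb <- ((seq_len(nb) - 1L) %/% binning$n_scale_bins) %% ns + 1L
  tibble::tibble(
    bin = seq_len(nb),
    dtype = binning$dtypes[((seq_len(nb) - 1L) %/%
                              (ns * binning$n_scale_bins)) + 1L],
    spatial_bin = as.integer(sb),
    scale_bin = ((seq_len(nb) - 1L) %% binning$n_scale_bins) + 1L,
    n_descriptors = as.integer(n_desc),
    ap = ap)
}
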