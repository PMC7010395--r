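#' Build an individual catalog from reference descriptor sets
#'
#' Stacks reference descriptors grouped by individual and prepares one exact
#' nearest-neighbour index per (descriptor type, filter scale) stratum.
#' Exact search is dense matrix algebra; an approximate backend can stand in
#' for scale, but the exact path is always available and is what the tests
#' pin down. Zero-flagged (degenerate) descriptors are excluded.
#'
#' @param refs a `descriptor_set` tibble (or `bind_rows` of several) with a
#'   non-`NA` `individual` column; an optional `bin` column (fin-space bin
#'   ids) is carried into the index for scoring-vector construction.
#' @param drop_unbinned drop descriptors whose `bin` is `NA` (required for
#'   fin-space scoring; leave `FALSE` for the plain LNBNN baseline).
#' @return an object of class `individual_catalog`: list with `classes` and
#'   `strata` (named list keyed `"<dtype>_<sigma>"`, each holding `mat`
#'   (descriptors x dims), `class`, `bin`).
#' @export
build_catalog <- function(refs, drop_unbinned = FALSE) {
  refs <- dplyr::filter(refs, !.data$zero)
  if (any(is.na(refs$individual))) {
    stop("all reference descriptors must carry an individual label")
  }
  has_bin <- "bin" %in% names(refs)
  if (drop_unbinned) {
    if (!has_bin) stop("no `bin` column to filter on")
    refs <- dplyr::filter(refs, !is.na(.data$bin))
  }
  classes <- sort(unique(refs$individual))
  if (length(classes) < 2L) {
    stop("a catalog needs at least 2 individuals (the out-of-class ",
         "nearest neighbour is undefined otherwise)")
  }
  key <- paste(refs$dtype, refs$sigma, sep = "_")
  strata <- lapply(split(seq_len(nrow(refs)), key), function(i) {
    list(mat = do.call(rbind, refs$vector[i]),
         class = refs$individual[i],
         bin = if (has_bin) refs$bin[i] else rep(NA_integer_, length(i)))
  })
  structure(list(classes = classes, strata = strata),
            class = "individual_catalog")
}

#' @export
print.individual_catalog <- function(x, ...) {
  cat(sprintf("<individual_catalog: %d individuals, strata: %s>\n",
              length(x$classes), paste(names(x$strata), collapse = ", ")))
  invisible(x)
}

# squared Euclidean distances between row sets (q x r)
sq_dists <- function(q, r) {
  d2 <- outer(rowSums(q^2), rowSums(r^2), "+") - 2 * tcrossprod(q, r)
  pmax(d2, 0)
}

# per-class nearest-neighbour table for one stratum: list with
#   d2min  (|DQ| x nclass) squared distance to the nearest ref of each class
#   ref    (|DQ| x nclass) row index (into stratum) of that nearest ref
class_nn <- function(qmat, stratum, classes) {
  d2 <- sq_dists(qmat, stratum$mat)
  nq <- nrow(qmat)
  d2min <- matrix(Inf, nq, length(classes))
  refidx <- matrix(NA_integer_, nq, length(classes))
  for (ci in seq_along(classes)) {
    cols <- which(stratum$class == classes[ci])
    if (length(cols) == 0L) next
    sub <- d2[, cols, drop = FALSE]
    w <- max.col(-sub, ties.method = "first")
    d2min[, ci] <- sub[cbind(seq_len(nq), w)]
    refidx[, ci] <- cols[w]
  }
  list(d2min = d2min, ref = refidx)
}

# LNBNN local match scores for one stratum: f(d, c) = max(0, d2(NN_other) -
# d2(NN_c)); returns |DQ| x nclass matrix (and keeps the matched-ref table)
stratum_scores <- function(qmat, stratum, classes) {
  nn <- class_nn(qmat, stratum, classes)
  nc <- length(classes)
  f <- matrix(0, nrow(qmat), nc)
  for (ci in seq_len(nc)) {
    other <- apply(nn$d2min[, -ci, drop = FALSE], 1L, min)
    f[, ci] <- pmax(other - nn$d2min[, ci], 0)
  }
  list(f = f, ref = nn$ref)
}

#' Local naive Bayes nearest-neighbour match score
#'
#' For a single query descriptor `d` and class `c`:
#' f(d, c) = delta(NN_otherclasses) - delta(NN_c) when positive, else 0,
#' where delta is the squared Euclidean distance to the nearest reference
#' descriptor. Descriptors that are no closer to class c than to the rest of
#' the population contribute nothing.
#'
#' @param d numeric descriptor vector.
#' @param class class (individual) label.
#' @param catalog an [build_catalog()] object.
#' @param dtype,sigma the stratum the descriptor belongs to.
#' @return a non-negative scalar.
#' @export
local_match_score <- function(d, class, catalog, dtype, sigma) {
  key <- paste(dtype, sigma, sep = "_")
  stratum <- catalog$strata[[key]]
  if (is.null(stratum)) stop("no catalog stratum for ", key)
  if (length(d) != ncol(stratum$mat)) {
    stop("descriptor length does not match the stratum index")
  }
  if (!class %in% catalog$classes) stop("unknown class: ", class)
  sc <- stratum_scores(matrix(d, 1L), stratum, catalog$classes)
  sc$f[1L, match(class, catalog$classes)]
}

#' Classify a query descriptor set by LNBNN
#'
#' Sums local match scores over the query's descriptors within each
#' (descriptor type, scale) stratum, then linearly combines strata with
#' weights `w` (all 1 by default, i.e. equal weighting). The predicted
#' identity is the score argmax, ties broken by class id.
#'
#' @param query a `descriptor_set` for one query image.
#' @param catalog an [build_catalog()] object.
#' @param weights named numeric vector of stratum weights (names
#'   `"<dtype>_<sigma>"`); unnamed scalar recycles to all strata.
#' @return a tibble of class `ranked_prediction`: `class`, `score`, `rank`,
#'   with attribute `query_id`.
#' @export
classify_lnbnn <- function(query, catalog, weights = NULL) {
  strata_keys <- names(catalog$strata)
  w <- rep(1, length(strata_keys))
  names(w) <- strata_keys
  if (!is.null(weights)) {
    if (is.null(names(weights))) {
      w[] <- rep(as.numeric(weights), length.out = length(w))
    } else {
      w[names(weights)] <- as.numeric(weights)
    }
  }
  query <- dplyr::filter(query, !.data$zero)
  total <- numeric(length(catalog$classes))
  if (nrow(query) == 0L) {
    warning("empty query descriptor set: uniform zero scores")
  } else {
    key <- paste(query$dtype, query$sigma, sep = "_")
    for (k in unique(key)) {
      if (!k %in% strata_keys) next
      qmat <- do.call(rbind, query$vector[key == k])
      sc <- stratum_scores(qmat, catalog$strata[[k]], catalog$classes)
      total <- total + w[[k]] * colSums(sc$f)
    }
  }
  qid <- if (nrow(query) > 0L) query$image_id[1L] else NA_character_
  out <- tibble::tibble(class = catalog$classes, score = total)
  out <- out[order(-out$score, out$class), ]
  out$rank <- seq_len(nrow(out))
  attr(out, "query_id") <- qid
  class(out) <- c("ranked_prediction", class(out))
  out
}

# average precision of a scored binary ranking: area under the PR step
# curve traced by descending score thresholds. Tied scores are collapsed
# into one threshold group, so the value never depends on input order.
average_precision <- function(scores, labels) {
  pos <- sum(labels)
  if (pos == 0L) return(NA_real_)
  ord <- order(-scores)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(vapply(split(l, grp), sum, numeric(1)))
  n <- cumsum(vapply(split(l, grp), length, integer(1)))
  prec <- tp / n
  rec <- tp / pos
  sum(diff(c(0, rec)) * prec)
}

#' Evaluate identification predictions
#'
#' AP pools every (query, class) score with label "class is the query's true
#' individual" and computes the area under the precision-recall curve traced
#' directly by the scores. mAP computes one AP per individual (over that
#' individual's class scores across all queries) and averages them
#' unweighted, which removes bias toward frequently-sighted individuals.
#'
#' @param predictions tibble with `query_id`, `class`, `score` (stacked
#'   [classify_lnbnn()]/[classify_finspace()] outputs).
#' @param truth tibble with `query_id`, `individual`.
#' @return an object of class `identification_evaluation`: list with `ap`,
#'   `map`, `top1`, `per_individual` (tibble), `pr` (pooled PR curve
#'   tibble), `n_queries`.
#' @export
evaluate_identification <- function(predictions, truth) {
  df <- dplyr::left_join(predictions,
                         dplyr::rename(truth, truth_ind = "individual"),
                         by = "query_id")
  if (any(is.na(df$truth_ind))) stop("queries missing from the truth table")
  df$label <- df$class == df$truth_ind
  ap <- average_precision(df$score, df$label)
  per <- df |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      ap = average_precision(.data$score, .data$label),
      n_queries = sum(.data$label), .groups = "drop")
  map <- mean(per$ap[per$n_queries > 0], na.rm = TRUE)
  top1 <- df |>
    dplyr::group_by(.data$query_id) |>
    dplyr::summarise(hit = .data$class[which.max(.data$score)] ==
                       .data$truth_ind[1L], .groups = "drop")
  ord <- order(-df$score)
  lab <- df$label[ord]
  pr <- tibble::tibble(recall = cumsum(lab) / sum(lab),
                       precision = cumsum(lab) / seq_along(lab))
  structure(list(ap = ap, map = map, top1 = mean(top1$hit),
                 per_individual = per, pr = pr,
                 n_queries = length(unique(df$query_id))),
            class = "identification_evaluation")
}

#' @export
print.identification_evaluation <- function(x, ...) {
  cat(sprintf(
    "<identification_evaluation: %d queries, AP = %.4f, mAP = %.4f, top-1 = %.3f>\n",
    x$n_queries, x$ap, x$map, x$top1))
  invisible(x)
}

#' @export
glance.identification_evaluation <- function(x, ...) {
  tibble::tibble(ap = x$ap, map = x$map, top1 = x$top1,
                 n_queries = x$n_queries)
}

#' @export
tidy.identification_evaluation <- function(x, ...) {
  x$per_individual
}
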