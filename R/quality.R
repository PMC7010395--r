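#' Random-forest stroke quality regressor
#'
#' Learns to predict the ground-truth quality of a stroke candidate (its
#' boundary-matching F-measure against the labelled fin contour) from its
#' 180-dimensional feature vector. Training is deterministic given `seed`.
#'
#' @param features numeric matrix of stroke feature vectors (rows).
#' @param targets ground-truth qualities in \[0, 1\], one per row.
#' @param ntree number of trees.
#' @param seed RNG seed.
#' @return an object of class `quality_regressor` wrapping the fitted
#'   forest, with the out-of-bag predictions kept for diagnostics.
#' @export
train_quality_regressor <- function(features, targets, ntree = 500L,
                                    seed = 1L) {
  features <- as.matrix(features)
  if (nrow(features) != length(targets)) {
    stop("features and targets disagree in length")
  }
  if (nrow(features) < 10L) stop("refusing to train on fewer than 10 samples")
  if (any(targets < 0 | targets > 1)) stop("targets must lie in [0, 1]")
  set.seed(seed)
  forest <- randomForest::randomForest(x = features, y = as.numeric(targets),
                                       ntree = ntree)
  structure(list(forest = forest, ntree = ntree, seed = seed,
                 oob = as.numeric(forest$predicted)),
            class = "quality_regressor")
}

#' Predict stroke quality scores
#'
#' @param model a [train_quality_regressor()] fit.
#' @param features feature matrix as used in training.
#' @return predicted qualities, clipped to \[0, 1\].
#' @export
score_strokes <- function(model, features) {
  p <- stats::predict(model$forest, as.matrix(features))
  pmin(pmax(as.numeric(p), 0), 1)
}

#' Persist and restore a quality regressor
#'
#' Round-trips bit-stably through `saveRDS`/`readRDS`.
#' @param model a `quality_regressor`.
#' @param path file path.
#' @return `save_quality_regressor` returns `path` invisibly;
#'   `load_quality_regressor` the restored model.
#' @export
save_quality_regressor <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_quality_regressor
#' @export
load_quality_regressor <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "quality_regressor")) stop("not a quality_regressor")
  model
}

#' @export
print.quality_regressor <- function(x, ...) {
  cat(sprintf("<quality_regressor: %d trees, %d training strokes>\n",
              x$ntree, length(x$oob)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.quality_regressor <- function(x, ...) {
  imp <- randomForest::importance(x$forest)
  tibble::tibble(feature = rownames(imp),
                 increase_node_purity = as.numeric(imp[, 1L]))
}

#' @export
glance.quality_regressor <- function(x, ...) {
  tibble::tibble(ntree = x$ntree,
                 n_train = length(x$oob),
                 oob_mse = mean((x$oob - x$forest$y)^2),
                 oob_rsq = 1 - mean((x$oob - x$forest$y)^2) /
                   stats::var(x$forest$y))
}
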