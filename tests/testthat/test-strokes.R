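# a pool of hand-made star boundaries, each yielding >= 7 keypoints
star_pool <- function(k = 12L, spikes = 8L) {
  out <- tibble::tibble(
    region_id = seq_len(k),
    boundary = lapply(seq_len(k), function(i) {
      star_curve(spikes = spikes, centre = c(100 * i, 0))
    }))
  out
}

test_that("stroke candidate generation counts follow (n^2 - n) k", {
  pool <- star_pool(12L)
  strokes <- generate_stroke_candidates(pool, n_keypoints = 7L)
  expect_equal(nrow(strokes), (7^2 - 7) * 12)   # 504 candidates

  # fewer than two keypoints contributes nothing
  expect_equal(nrow(generate_stroke_candidates(star_pool(1L),
                                               n_keypoints = 1L)), 0L)
})

test_that("complementary arcs of a keypoint pair tile the boundary", {
  pool <- star_pool(1L, spikes = 3L)
  strokes <- generate_stroke_candidates(pool, n_keypoints = 3L)
  expect_equal(nrow(strokes), 6L)
  nb <- nrow(pool$boundary[[1L]]$points)
  for (i in unique(strokes$start_idx)) {
    for (j in unique(strokes$end_idx)) {
      if (i == j) next
      fwd <- strokes[strokes$start_idx == i & strokes$end_idx == j, ]
      bwd <- strokes[strokes$start_idx == j & strokes$end_idx == i, ]
      if (nrow(fwd) == 0L || nrow(bwd) == 0L) next
      covered <- c(fwd$path[[1L]]$points[, 1L], bwd$path[[1L]]$points[, 1L])
      # arcs share their two endpoints and cover every boundary vertex once
      expect_equal(length(covered), nb + 2L)
    }
  }
  # every stroke is a contiguous arc of the boundary
  bpts <- pool$boundary[[1L]]$points
  for (r in seq_len(nrow(strokes))) {
    p <- strokes$path[[r]]$points
    expect_true(all(p[, 1L] %in% bpts[, 1L]))
  }
})

test_that("the normals histogram is direction-dependent and analytic on
           simple shapes", {
  flat <- planar_curve(cbind(seq(0, 39), rep(0, 40)))
  hist <- normals_histogram(flat)
  m <- matrix(hist, nrow = 8L)   # orientation x spatial
  occupied_orients <- which(rowSums(m) > 0)
  expect_length(occupied_orients, 1L)
  expect_equal(as.numeric(colSums(m) > 0), rep(1, 20))
  expect_equal(sum(hist^2), 1, tolerance = 1e-12)

  # reversal rotates every normal by pi = 4 orientation bins
  rev_flat <- planar_curve(flat$points[40:1, ])
  hist_rev <- normals_histogram(rev_flat)
  expect_false(isTRUE(all.equal(hist, hist_rev)))
  m_rev <- matrix(hist_rev, nrow = 8L)
  expect_equal(m_rev[((occupied_orients + 3L) %% 8L) + 1L, ],
               m[occupied_orients, ], tolerance = 1e-12)

  # semicircular arc vs analytically binned normals
  th <- seq(0, pi, length.out = 200L)
  arc <- planar_curve(cbind(50 * cos(th), 50 * sin(th)))
  got <- matrix(normals_histogram(arc), nrow = 8L)
  # outward normal at angle th points along (cos th, sin th) rotated by the
  # traversal convention; bin membership must vary smoothly over 4 of the 8
  # orientation bins for a half turn
  expect_equal(sum(colSums(got) > 0), 20L)
  expect_equal(sum(rowSums(got) > 0), 4L)

  expect_error(normals_histogram(planar_curve(cbind(0:9, 0))), "at least")
})

test_that("greedy stroke NMS matches an exhaustive oracle", {
  seg <- function(x0, n = 30L) {
    curve_unchecked(cbind(seq(x0, x0 + n - 1L), rep(0, n)))
  }
  # identical strokes: one survives
  two <- tibble::tibble(score = c(0.9, 0.8),
                        path = list(seg(0), seg(0)))
  expect_equal(nrow(stroke_nms(two)), 1L)
  # disjoint strokes: both survive
  far <- tibble::tibble(score = c(0.9, 0.8),
                        path = list(seg(0), seg(100)))
  expect_equal(nrow(stroke_nms(far)), 2L)

  # 5-stroke fixture vs a literal greedy re-implementation
  paths <- list(seg(0), seg(5), seg(40), seg(43), seg(90))
  scores <- c(0.95, 0.6, 0.8, 0.85, 0.3)
  fx <- tibble::tibble(score = scores, path = paths)
  got <- stroke_nms(fx, overlap_thresh = 0.2, tol = 2)
  pix <- lapply(paths, rasterise_curve)
  ov <- function(i, j) {
    m <- oracle_matching_size(pix[[i]], pix[[j]], 2)
    m / min(nrow(pix[[i]]), nrow(pix[[j]]))
  }
  kept <- integer(0)
  for (i in order(-scores)) {
    if (all(vapply(kept, function(j) ov(i, j) <= 0.2, logical(1)))) {
      kept <- c(kept, i)
    }
  }
  expect_equal(sort(got$score), sort(scores[kept]))
})

test_that("appearance bags are direction-independent and match a
           brute-force assignment oracle", {
  set.seed(31)
  img <- array(stats::runif(60 * 60 * 3), c(60L, 60L, 3L))
  stroke <- planar_curve(cbind(seq(15, 45), rep(30, 31)))
  dict <- train_visual_dictionary(list(img), n_words = 2L,
                                  patch_sizes = c(8L, 12L),
                                  n_sample = 100L, seed = 2)
  expect_equal(nrow(dict$centers), 2L)
  bag <- appearance_bag(img, stroke, dict)
  rev_stroke <- planar_curve(stroke$points[31:1, ])
  expect_equal(appearance_bag(img, rev_stroke, dict), bag,
               tolerance = 1e-12)

  # uniform image: every descriptor identical, one-hot histogram
  uni <- array(0.5, c(40L, 40L, 3L))
  bag_u <- appearance_bag(uni, planar_curve(cbind(seq(10, 30), 20)), dict)
  expect_equal(sort(bag_u), c(0, 1))

  # brute-force per-pixel assignment oracle
  ch <- opponent_channels(img)
  pix <- rasterise_curve(stroke)
  offs <- expand.grid(dx = -4:4, dy = -4:4)
  offs <- offs[offs$dx^2 + offs$dy^2 <= 16, ]
  band <- unique(do.call(rbind, lapply(seq_len(nrow(pix)), function(i) {
    cbind(pix[i, 1L] + offs$dx, pix[i, 2L] + offs$dy)
  })))
  band <- band[band[, 1L] >= 1 & band[, 1L] <= 60 &
                 band[, 2L] >= 1 & band[, 2L] <= 60, ]
  counts <- numeric(2L)
  for (ps in dict$patch_sizes) {
    half <- ps %/% 2L
    for (r in seq_len(nrow(band))) {
      cx <- band[r, 1L]; cy <- band[r, 2L]
      rows <- max(1L, cy - half):min(60L, cy + half)
      cols <- max(1L, cx - half):min(60L, cx + half)
      d <- unlist(lapply(ch, function(m) {
        v <- m[rows, cols]
        c(mean(v), sqrt(max(mean(v^2) - mean(v)^2, 0)))
      }))
      d2 <- colSums((t(dict$centers) - d)^2)
      counts[which.min(d2)] <- counts[which.min(d2)] + 1
    }
  }
  expect_equal(bag, counts / sqrt(sum(counts^2)), tolerance = 1e-9)
})

test_that("stroke features concatenate to 180 dims and feed the quality
           regressor", {
  set.seed(7)
  img <- array(stats::runif(50 * 50 * 3), c(50L, 50L, 3L))
  dict <- train_visual_dictionary(list(img), n_words = 20L,
                                  patch_sizes = c(8L, 12L),
                                  n_sample = 80L, seed = 5)
  strokes <- tibble::tibble(
    region_id = 1L,
    path = lapply(seq(5, 40, by = 5), function(y) {
      planar_curve(cbind(seq(5, 44), rep(y, 40)))
    }))
  feats <- stroke_features(img, strokes, dict, stride = 2L)
  expect_equal(dim(feats), c(8L, 180L))
  expect_true(all(abs(rowSums(feats[, 1:20, drop = FALSE]^2) - 1) < 1e-9))
  expect_true(all(abs(rowSums(feats[, 21:180, drop = FALSE]^2) - 1) < 1e-9))
})

test_that("the quality regressor fits, ranks and persists deterministically", {
  expect_error(train_quality_regressor(matrix(0, 5, 3), rep(0.5, 5)),
               "fewer than 10")
  # constant target: predictions collapse to the constant
  set.seed(1)
  x <- matrix(stats::runif(600), 30L)
  m_const <- suppressWarnings(
    train_quality_regressor(x, rep(0.4, 30L), ntree = 50L))
  expect_equal(score_strokes(m_const, x), rep(0.4, 30L), tolerance = 1e-9)

  # separable fixture: fin-like strokes have mass in one block
  set.seed(2)
  n <- 120L
  quality <- stats::runif(n)
  feats <- cbind(matrix(quality + stats::rnorm(n * 5L, 0, 0.1), n, 5L),
                 matrix(stats::runif(n * 15L), n, 15L))
  fit <- train_quality_regressor(feats, pmin(pmax(quality, 0), 1),
                                 ntree = 200L, seed = 3)
  expect_gt(stats::cor(fit$oob, quality, method = "spearman"), 0.8)

  path <- withr::local_tempfile(fileext = ".rds")
  save_quality_regressor(fit, path)
  back <- load_quality_regressor(path)
  expect_identical(score_strokes(back, feats), score_strokes(fit, feats))

  expect_s3_class(generics::glance(fit), "tbl_df")
  expect_equal(nrow(generics::tidy(fit)), 20L)
})
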