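test_that("planar_curve validates its invariants", {
  expect_error(planar_curve(cbind(0:1, 0:1)), "at least 3")
  expect_error(planar_curve(cbind(c(0, 0, 1), c(0, 0, 1))), "duplicate")
  expect_error(planar_curve(cbind(c(0, 1, 0), c(0, 1, 0)), closed = TRUE),
               "repeat")
  crv <- planar_curve(cbind(c(0, 1, 1), c(0, 0, 1)))
  expect_s3_class(crv, "planar_curve")
  expect_false(crv$closed)
})

test_that("resampling is uniform in arc length and preserves endpoints", {
  line <- planar_curve(cbind(c(0, 3, 10), c(0, 0, 0)))
  rs <- resample_curve(line, 11L)
  expect_equal(rs$points[, "x"], 0:10, tolerance = 1e-12)
  expect_equal(rs$points[, "y"], rep(0, 11))

  # refinement preserves total length within 1%
  set.seed(4)
  th <- 2 * pi * (0:31) / 32
  crv <- planar_curve(cbind((10 + stats::runif(32, -1, 1)) * cos(th),
                            (10 + stats::runif(32, -1, 1)) * sin(th)),
                      closed = TRUE)
  up <- resample_curve(crv, 128L)
  expect_lt(abs(curve_length(up) - curve_length(crv)) / curve_length(crv),
            0.01)

  # independent cumulative-arc-length interpolation oracle on an irregular
  # 5-point polyline
  p <- cbind(c(0, 2, 3, 7, 8), c(0, 1, -1, 0, 4))
  poly <- planar_curve(p)
  out <- resample_curve(poly, 8L)
  seglen <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seglen))
  targets <- seq(0, s[5L], length.out = 8L)
  expected <- t(vapply(targets, function(tt) {
    i <- max(which(s <= tt + 1e-15)); i <- min(i, 4L)
    f <- (tt - s[i]) / seglen[i]
    p[i, ] + f * (p[i + 1L, ] - p[i, ])
  }, numeric(2)))
  expect_equal(unname(out$points), unname(expected), tolerance = 1e-9)

  expect_error(resample_curve(planar_curve(cbind(c(0, 1, 0), c(0, 0, 1))),
                              2L), "n_samples")
})

test_that("gaussian smoothing shrinks circles, fixes constants, matches a
           naive convolution oracle", {
  n <- 64L
  th <- 2 * pi * (seq_len(n) - 1L) / n
  circ <- planar_curve(cbind(5 * cos(th), 5 * sin(th)), closed = TRUE)
  sm <- gaussian_smooth(circ, 2)
  radii <- sqrt(rowSums(sm$points^2))
  expect_true(all(radii <= 5 + 1e-12))
  expect_lt(diff(range(radii)), 1e-9)   # still concentric

  flat <- planar_curve(cbind(rep(3, 16) + 0, seq_len(16L)))
  smf <- gaussian_smooth(flat, 1.5)
  expect_equal(smf$points[, "x"], rep(3, 16), tolerance = 1e-12)

  crv <- random_closed_curve(64L, seed = 9)
  got <- gaussian_smooth(crv, 2.3)
  expect_equal(got$points[, "x"],
               oracle_convolve(crv$points[, "x"], 2.3, TRUE),
               tolerance = 1e-9)
  expect_equal(got$points[, "y"],
               oracle_convolve(crv$points[, "y"], 2.3, TRUE),
               tolerance = 1e-9)

  # sub-sample sigma returns the input within interpolation tolerance
  tiny <- gaussian_smooth(crv, 0.05)
  expect_lt(max(abs(tiny$points - crv$points)), 1e-6)
})

test_that("DoG corner response matches its composition oracle and geometry", {
  # straight line: vertices beyond the filter support of the open ends
  # respond exactly zero (symmetric unit-mass kernels reproduce linears)
  line <- planar_curve(cbind(seq(0, 100), 2 * seq(0, 100)))
  d <- dog_response(line, 1, 4)
  interior <- 20:80   # > 4 * m * sigma = 16 samples from either end
  expect_lt(max(d$values[interior]), 1e-9)

  # circle: constant response by rotational symmetry
  n <- 64L
  th <- 2 * pi * (seq_len(n) - 1L) / n
  circ <- planar_curve(cbind(7 * cos(th), 7 * sin(th)), closed = TRUE)
  dc <- dog_response(circ, 1.5, 4)
  expect_lt(diff(range(dc$values)), 1e-9)

  # 128-point square vs two-independent-smoothings oracle
  sq <- resample_curve(planar_curve(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)),
                                    closed = TRUE), 128L)
  got <- dog_response(sq, 1, 4)
  expect_equal(got$values, oracle_dog(sq$points, 1, 4, TRUE),
               tolerance = 1e-9)

  expect_warning(dog_response(circ, 1, 1), "identically zero")

  # rigid-motion invariance
  crv <- random_closed_curve(96L, seed = 2)
  ang <- 0.83
  rot <- cbind(cos(ang) * crv$points[, 1L] - sin(ang) * crv$points[, 2L] + 11,
               sin(ang) * crv$points[, 1L] + cos(ang) * crv$points[, 2L] - 4)
  moved <- planar_curve(rot, closed = TRUE)
  expect_lt(max(abs(dog_response(moved, 2, 4)$values -
                      dog_response(crv, 2, 4)$values)), 1e-9)
})

test_that("keypoint prominences follow the interval rule exactly", {
  # a single interior maximum of height h on an open signal has prominence h
  v <- c(0, 1, 5, 2, 1)
  kp <- find_keypoints(v, 3L)
  expect_equal(kp$index, 3L)
  expect_equal(kp$prominence, 5)

  expect_equal(nrow(find_keypoints(rep(2, 30), 5L)), 0L)

  # exhaustive oracle over random signals, open and circular
  for (seed in 1:8) {
    set.seed(seed)
    v <- round(stats::runif(64), 3)
    for (closed in c(FALSE, TRUE)) {
      got <- find_keypoints(v, 5L, closed = closed)
      orc <- oracle_prominences(v, closed)
      ord <- order(-orc$prominences, orc$peaks)
      keep <- ord[seq_len(min(5L, length(ord)))]
      expect_equal(got$index, orc$peaks[keep])
      expect_equal(got$prominence, orc$prominences[keep], tolerance = 1e-12)
    }
  }

  # adding a constant never changes circular keypoints, nor interior-peak
  # ordering on open signals
  set.seed(42)
  v <- stats::runif(48)
  a <- find_keypoints(v, 6L, closed = TRUE)
  b <- find_keypoints(v + 3.7, 6L, closed = TRUE)
  expect_equal(a$index, b$index)
  expect_equal(a$prominence, b$prominence, tolerance = 1e-12)
})
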