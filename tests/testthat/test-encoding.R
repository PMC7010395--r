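# an open fin-like arc with `n_notch` sharp notches planted on it
notched_fin <- function(n_notch = 8L, n = 600L, depth = 4) {
  t <- seq(0, pi, length.out = n)
  x <- 100 * cos(t) ; y <- 60 * sin(t)
  pos <- seq(0.15, 0.85, length.out = n_notch)
  d <- rowSums(vapply(pos, function(p0) {
    depth * exp(-(seq(0, 1, length.out = n) - p0)^2 / (2 * 0.004^2))
  }, numeric(n)))
  planar_curve(cbind(x, y - d))
}

test_that("fin keypointing finds planted notches and respects the cap", {
  fin <- fin_contour(notched_fin(8L), image_id = "fx")
  kps <- extract_fin_keypoints(fin, n = 50L)
  expect_lte(nrow(kps), 50L)

  # every planted notch apex has a keypoint within 2% of contour length;
  # expected positions re-derived in arc length from the raw template
  raw <- notched_fin(8L)
  s_raw <- c(0, cumsum(sqrt(rowSums(diff(raw$points)^2))))
  n_raw <- nrow(raw$points)
  notch_arc <- s_raw[round(seq(0.15, 0.85, length.out = 8L) *
                             (n_raw - 1L)) + 1L] / s_raw[n_raw]
  kp_pos <- (kps$index - 1L) / 1023
  for (p0 in notch_arc) {
    expect_lt(min(abs(kp_pos - p0)), 0.02)
  }

  # a straight "fin" has no interior response maxima of any prominence
  straight <- fin_contour(planar_curve(cbind(seq(0, 500, length.out = 600),
                                             rep(0, 600))))
  kp0 <- extract_fin_keypoints(straight, n = 50L)
  expect_true(all(kp0$prominence < 1e-12))
})

test_that("subsection generation is combinatorial in the keypoints", {
  fin <- fin_contour(notched_fin(6L))
  kp50 <- tibble::tibble(index = as.integer(seq(8, 1015, length.out = 50L)),
                         prominence = rep(1, 50L))
  subs <- generate_subsections(fin, kp50)
  expect_equal(nrow(subs), choose(50, 2))   # 1225
  both <- generate_subsections(fin, kp50, both_directions = TRUE)
  expect_equal(nrow(both), 2L * 1225L)

  kp3 <- tibble::tibble(index = c(100L, 500L, 900L), prominence = rep(1, 3))
  s3 <- generate_subsections(fin, kp3)
  expect_equal(nrow(s3), 3L)
  for (i in seq_len(3L)) {
    p <- s3$path[[i]]$points
    expect_equal(nrow(p), 256L)
    # contiguous arc: path endpoints sit on the keypoint vertices
    expect_equal(unname(p[1L, ]),
                 unname(fin$path$points[s3$start_kp[i], ]), tolerance = 1e-9)
    expect_equal(unname(p[256L, ]),
                 unname(fin$path$points[s3$end_kp[i], ]), tolerance = 1e-9)
  }
  expect_equal(nrow(generate_subsections(fin, kp3[0, ])), 0L)
})

test_that("DoG-norm descriptors are rigid-motion invariant and match the
           composition oracle", {
  fin <- fin_contour(notched_fin(5L))
  kp <- tibble::tibble(index = c(120L, 520L, 880L), prominence = rep(1, 3))
  subs <- generate_subsections(fin, kp)
  path <- subs$path[[2L]]

  d <- dogn_descriptor(path, 4)
  expect_false(d$zero)
  expect_equal(sum(d$vector^2), 1, tolerance = 1e-9)

  ang <- 1.1
  rot <- curve_unchecked(cbind(
    cos(ang) * path$points[, 1L] - sin(ang) * path$points[, 2L] + 40,
    sin(ang) * path$points[, 1L] + cos(ang) * path$points[, 2L] - 7))
  d_rot <- dogn_descriptor(rot, 4)
  expect_lt(max(abs(d_rot$vector - d$vector)), 1e-6)

  # oracle: two independent smoothings, squared difference, L2
  orc <- oracle_dog(path$points, 4, 2, closed = FALSE)
  expect_equal(d$vector, orc / sqrt(sum(orc^2)), tolerance = 1e-9)

  straight <- resample_curve(planar_curve(cbind(0:40, 0)), 256L)
  dz <- dogn_descriptor(straight, 2)
  expect_true(dz$zero)
  expect_true(all(dz$vector == 0))
})

test_that("normal descriptors align, de-rotate and match analytic normals", {
  straight <- resample_curve(planar_curve(cbind(0:40, 0)), 64L)
  nd <- normal_descriptor(straight, 1)
  n <- 64L
  nx <- nd$vector[seq_len(n)]
  ny <- nd$vector[n + seq_len(n)]
  # all normals identical unit vectors after alignment: components constant
  expect_lt(diff(range(nx)), 1e-9)
  expect_lt(diff(range(ny)), 1e-9)
  expect_equal(sqrt(sum(nd$vector^2)), 1, tolerance = 1e-9)

  fin <- fin_contour(notched_fin(5L))
  kp <- tibble::tibble(index = c(120L, 520L, 880L), prominence = rep(1, 3))
  path <- generate_subsections(fin, kp)$path[[1L]]
  base <- normal_descriptor(path, 2)
  ang <- -0.7
  rot <- curve_unchecked(cbind(
    cos(ang) * path$points[, 1L] - sin(ang) * path$points[, 2L] + 3,
    sin(ang) * path$points[, 1L] + cos(ang) * path$points[, 2L] + 90))
  expect_lt(max(abs(normal_descriptor(rot, 2)$vector - base$vector)), 1e-6)

  # semicircular arc: smoothed-curve normals stay radial (up to boundary
  # effects), so the two components follow cos/sin of the arc parameter
  th <- seq(0, pi, length.out = 256L)
  arc <- curve_unchecked(cbind(50 * cos(th), 50 * sin(th)))
  na <- normal_descriptor(arc, 2)
  nx <- na$vector[1:256] ; ny <- na$vector[257:512]
  ang_got <- atan2(ny[30:226], nx[30:226])
  # angles must sweep monotonically, covering the interior arc span
  # (samples 30..226 of a half turn subtend about 2.4 radians)
  expect_true(all(diff(ang_got) < 0) || all(diff(ang_got) > 0))
  expect_gt(abs(ang_got[197] - ang_got[1]), 2.2)

  expect_error(normal_descriptor(curve_unchecked(
    cbind(c(0, 1, 0), c(0, 1, 0))), 1), "coincident")

  # literal smoothed-coordinate variant stays available and differs
  alt <- normal_descriptor(path, 2, variant = "smoothed_coords")
  expect_equal(sqrt(sum(alt$vector^2)), 1, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(alt$vector, base$vector)))
})

test_that("encode_fin produces the full descriptor grid with arc metadata", {
  fin <- fin_contour(notched_fin(6L), image_id = "imgA")
  enc <- encode_fin(fin, scales = c(2, 8), types = c("dogn", "normal"),
                    n_keypoints = 6L)
  n_subs <- length(unique(enc$sub_id))
  expect_equal(nrow(enc), n_subs * 2L * 2L)
  expect_setequal(unique(enc$sigma), c(2, 8))

  ref <- encode_fin(fin, scales = c(2, 8), types = "dogn",
                    n_keypoints = 6L, both_directions = TRUE)
  expect_equal(nrow(ref), 2L * n_subs * 2L)

  # p metadata equals an independent arc-length ratio computation
  s <- c(0, cumsum(sqrt(rowSums(diff(fin$path$points)^2))))
  for (r in sample(seq_len(nrow(enc)), 10L)) {
    i <- min(enc$start_kp[r], enc$end_kp[r])
    j <- max(enc$start_kp[r], enc$end_kp[r])
    expect_equal(enc$p[r], (s[j] - s[i]) / s[1024L], tolerance = 1e-9)
  }

  # reversed-direction bookkeeping: the reverse descriptor of a subsection
  # equals the forward descriptor of its reversed path
  fwd_row <- which(ref$direction == "fwd")[1L]
  rev_row <- which(ref$direction == "rev" &
                     ref$sub_id == ref$sub_id[fwd_row] + 1L &
                     ref$sigma == ref$sigma[fwd_row])[1L]
  expect_false(isTRUE(all.equal(ref$vector[[fwd_row]],
                                ref$vector[[rev_row]])))

  # determinism
  enc2 <- encode_fin(fin, scales = c(2, 8), types = c("dogn", "normal"),
                     n_keypoints = 6L)
  expect_identical(enc$vector, enc2$vector)
})

test_that("the edge-refinement hook is identity by default and validated", {
  fin <- notched_fin(4L)
  img <- matrix(0.5, 10, 10)
  expect_identical(refine_contour(img, fin), fin)
  smoother <- function(image, crv) gaussian_smooth(crv, 1)
  out <- refine_contour(img, fin, hook = smoother)
  expect_false(isTRUE(all.equal(out$points, fin$points)))
  expect_error(refine_contour(img, fin, hook = function(i, c) "bad"),
               "must return")
})
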