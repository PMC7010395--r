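test_that("spatial bin enumeration counts contiguous partition runs", {
  expect_equal(nrow(enumerate_spatial_bins(5L)), 55L)
  b1 <- enumerate_spatial_bins(1L)
  expect_equal(nrow(b1), 3L)     # {1}, {2}, {1,2}
  b3 <- enumerate_spatial_bins(3L)
  # brute-force enumeration of runs over 6 ordered partitions
  runs <- 0L
  for (i in 1:6) for (j in i:6) runs <- runs + 1L
  expect_equal(nrow(b3), runs)   # 21
  expect_true(all(b3$first_part <= b3$last_part))

  binning <- fin_space_binning()
  expect_equal(n_bins(binning), 550L)     # 2 x 55 x 5
  expect_length(binning$scale_edges, 6L)
  expect_error(fin_space_binning(scale_edges = c(1, 2)), "entries")
})

test_that("tip localisation finds the apex and honours overrides", {
  # symmetric triangle: apex is the unique coarse curvature maximum
  up <- seq(0, 1, length.out = 300L)
  tri <- planar_curve(cbind(c(up * 50, 50 + up[-1L] * 50),
                            c(up * 80, 80 - up[-1L] * 80)))
  fin <- fin_contour(tri)
  expect_lt(abs(locate_tip(fin) - 0.5), 0.02)
  expect_equal(locate_tip(fin, override = 0.37), 0.37)

  # synthetic fins carry a ground-truth tip; the detector lands within 2%
  pop <- make_population(3L, seed = 14)
  for (i in 1:3) {
    sg <- render_sighting(pop[i, ], NULL, render = FALSE)
    f <- fin_contour(sg$contour)
    expect_lt(abs(locate_tip(f) - sg$tip), 0.02)
  }
})

test_that("bin assignment follows the more-than-half occupancy rule", {
  binning <- fin_space_binning()
  tip <- 0.5   # partitions are then runs of width 0.1
  mkdesc <- function(a, b, sigma = 4, dtype = "dogn", p = b - a) {
    tibble::tibble(start_pos = a, end_pos = b, p = p,
                   dtype = dtype, sigma = sigma)
  }
  # covering partitions {2,3,4} fully selects that exact 3-partition run
  got <- assign_bin(mkdesc(0.1, 0.4), binning, tip)
  run <- binning$spatial[binning$spatial$spatial_bin == got$spatial_bin, ]
  expect_equal(c(run$first_part, run$last_part), c(2L, 4L))

  # the whole fin maps to the maximal 10-partition run
  whole <- assign_bin(mkdesc(0, 1, p = 1), binning, tip)
  runw <- binning$spatial[binning$spatial$spatial_bin == whole$spatial_bin, ]
  expect_equal(c(runw$first_part, runw$last_part), c(1L, 10L))

  # a sliver occupying no partition more than half stays unbinned
  tiny <- assign_bin(mkdesc(0.31, 0.35, p = 0.04), binning, tip)
  expect_true(is.na(tiny$bin))

  # exactly half is excluded (strict rule)
  half <- assign_bin(mkdesc(0.30, 0.35, p = 0.05), binning, tip)
  expect_true(is.na(half$bin))

  # randomised subsections agree with a literal interval-overlap oracle
  set.seed(77)
  for (rep in 1:40) {
    a <- stats::runif(1, 0, 0.95)
    b <- min(1, a + stats::runif(1, 0.01, 0.6))
    sg <- sample(c(1, 2, 4, 8), 1L)
    d <- assign_bin(mkdesc(a, b, sigma = sg), binning, tip)
    starts <- seq(0, 1, by = 0.1)[1:10]
    occ <- which(pmin(b, starts + 0.1) - pmax(a, starts) > 0.05)
    if (length(occ) == 0L) {
      expect_true(is.na(d$bin))
    } else {
      run <- binning$spatial[binning$spatial$spatial_bin == d$spatial_bin, ]
      expect_equal(c(run$first_part, run$last_part),
                   c(min(occ), max(occ)))
      sigma_g <- sg / 256 * (b - a)
      edges <- binning$scale_edges
      sb <- max(1L, min(5L, findInterval(sigma_g, edges, left.open = TRUE)))
      expect_equal(d$scale_bin, sb)
    }
  }
})

make_finspace_fixture <- function(seed = 33) {
  ds <- make_dataset(5L, 3L, preset = "easy", seed = seed)
  refs <- encode_dataset(ds, "reference", types = "dogn", scales = c(2, 8),
                         n_keypoints = 8L)
  queries <- encode_dataset(ds, "query", types = "dogn", scales = c(2, 8),
                            n_keypoints = 8L)
  binning <- fin_space_binning(dtypes = "dogn", sigma_set = c(2, 8))
  ref_ids <- unique(refs$image_id)
  binned <- dplyr::bind_rows(lapply(ref_ids, function(id) {
    assign_bin(refs[refs$image_id == id, ], binning, tip = ds$tips[[id]])
  }))
  list(ds = ds, refs = binned, queries = queries, binning = binning,
       catalog = build_catalog(binned, drop_unbinned = TRUE))
}

test_that("scoring vectors conserve the LNBNN class score", {
  fx <- make_finspace_fixture()
  q1 <- fx$queries[fx$queries$image_id == fx$queries$image_id[1L], ]
  m <- scoring_matrix(q1, fx$catalog, fx$binning)
  expect_equal(dim(m), c(5L, n_bins(fx$binning)))
  expect_true(all(m >= 0))
  # conservation: row sums equal the Eq-style class scores over the same
  # binned catalog, to 1e-9
  lnbnn <- classify_lnbnn(q1, fx$catalog)
  expect_equal(rowSums(m)[match(lnbnn$class, fx$catalog$classes)],
               lnbnn$score, tolerance = 1e-9, ignore_attr = TRUE)

  # single matching pair: one-hot vector at the matched reference's bin
  ref1 <- fx$refs[!fx$refs$zero & !is.na(fx$refs$bin), ][1L, ]
  probe <- ref1
  probe$individual <- NA_character_
  probe$image_id <- "probe"
  v <- build_scoring_vector(probe, ref1$individual, fx$catalog, fx$binning)
  expect_equal(sum(v > 0), 1L)
  expect_gt(v[ref1$bin], 0)

  # a query with no positive scores yields the zero vector
  zeroq <- probe
  zeroq$vector <- list(rep(1e6, length(probe$vector[[1L]])))
  vz <- scoring_matrix(zeroq, fx$catalog, fx$binning)
  expect_true(all(vz == 0) || all(rowSums(vz > 0) <= 1))
})

test_that("per-descriptor accumulation matches a brute-force oracle", {
  fx <- make_finspace_fixture()
  q1 <- fx$queries[fx$queries$image_id == fx$queries$image_id[1L], ][1:6, ]
  cl <- fx$catalog$classes[2L]
  got <- build_scoring_vector(q1, cl, fx$catalog, fx$binning)
  # oracle: loop descriptors, exhaustive distances, accumulate at the bin of
  # the nearest same-class reference
  expected <- numeric(n_bins(fx$binning))
  for (i in seq_len(nrow(q1))) {
    if (q1$zero[i]) next
    key <- q1$dtype[i] == fx$refs$dtype & q1$sigma[i] == fx$refs$sigma &
      !fx$refs$zero & !is.na(fx$refs$bin)
    rr <- fx$refs[key, ]
    d2 <- vapply(rr$vector, function(v) sum((v - q1$vector[[i]])^2),
                 numeric(1))
    inc <- rr$individual == cl
    dc <- min(d2[inc]); do <- min(d2[!inc])
    if (do > dc) {
      bin <- rr$bin[which(inc)[which.min(d2[inc])]]
      expected[bin] <- expected[bin] + (do - dc)
    }
  }
  expect_equal(got, expected, tolerance = 1e-9)
})

test_that("the match classifier trains by-individual folds without leakage", {
  fx <- make_finspace_fixture()
  rows <- scoring_rows(fx$queries, fx$catalog, fx$binning)
  expect_error(train_match_classifier(rows[rows$individual ==
                                             rows$individual[1L], ]),
               "at least 4")
  model <- train_match_classifier(rows, ntree = 100L, seed = 4)
  # folds partition the individuals; no individual appears in both
  expect_setequal(model$folds$individual, unique(rows$individual))
  expect_equal(anyDuplicated(model$folds$individual), 0L)
  by_row <- model$folds$fold[match(model$cv$individual,
                                   model$folds$individual)]
  expect_identical(model$cv$fold, by_row)
  expect_true(all(!is.na(model$cv$prob)))

  # easy-regime fixture is separable: held-out match probabilities rank
  # true pairs clearly above impostors
  expect_gt(average_precision(model$cv$prob, model$cv$label), 0.9)

  g <- generics::glance(model)
  expect_equal(g$n_individuals, 5L)

  # classification through fin space: ranked, ties broken by class id
  q1 <- fx$queries[fx$queries$image_id == fx$queries$image_id[1L], ]
  pred <- classify_finspace(q1, fx$catalog, model, fx$binning)
  expect_equal(nrow(pred), 5L)
  expect_equal(pred$rank, 1:5)
})

test_that("bin distinctiveness reduces to the global AP for a single bin", {
  fx <- make_finspace_fixture()
  qids <- unique(fx$queries$image_id)[1:4]
  qs <- fx$queries[fx$queries$image_id %in% qids, ]
  qs_binned <- dplyr::bind_rows(lapply(qids, function(id) {
    assign_bin(qs[qs$image_id == id, ], fx$binning,
               tip = fx$ds$tips[[id]])
  }))
  tab <- measure_bin_distinctiveness(fx$catalog, qs_binned, fx$binning)
  expect_equal(nrow(tab), n_bins(fx$binning))
  expect_true(all(is.na(tab$ap[tab$n_descriptors == 0L])))
  expect_true(all(tab$ap >= 0 & tab$ap <= 1, na.rm = TRUE))

  # force every descriptor into one bin: per-bin AP equals the global
  # subsection-level AP
  one <- qs_binned
  one$bin <- 1L
  tab1 <- measure_bin_distinctiveness(fx$catalog, one, fx$binning)
  scores <- c(); labels <- c()
  for (qid in qids) {
    q <- qs_binned[qs_binned$image_id == qid, ]
    for (i in seq_len(nrow(q))) {
      if (q$zero[i]) next
      f <- vapply(fx$catalog$classes, function(cl) {
        local_match_score(q$vector[[i]], cl, fx$catalog,
                          q$dtype[i], q$sigma[i])
      }, numeric(1))
      scores <- c(scores, f)
      labels <- c(labels, fx$catalog$classes == q$individual[i])
    }
  }
  expect_equal(tab1$ap[1L], oracle_ap(scores, labels), tolerance = 1e-9)
})
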