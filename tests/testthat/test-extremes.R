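test_that("threshold crossing on the z-normalized group average defines extremes", {
  # construct a condition whose grand-average series is exactly a chosen
  # vector: two participants, two fROIs, all equal to g
  g <- c(0.2, 1.5, -0.3, 1.01, -1.2)
  gz <- (g - mean(g)) / sd(g)
  # pick raw values whose z-normalization yields peaks at the same spots:
  # use g itself scaled so z-normalized crossing matches direct values
  mats <- list(A = cbind(p1 = g, p2 = g), B = cbind(p1 = g, p2 = g))
  tcs <- make_tcs(mats)
  pk <- detect_extremes(tcs, "c1", "peak", threshold = 1)
  tr <- detect_extremes(tcs, "c1", "trough", threshold = 1)
  expect_equal(pk$indices, which(gz > 1))
  expect_equal(tr$indices, which(gz < -1))
  expect_equal(pk$group_series, gz)

  # strict inequality: values landing exactly on the threshold are excluded.
  # this vector is exactly mean 0, sd 1, with entries at exactly +/-1
  w <- c(1, -1, 1, -1, sqrt(0.5), -sqrt(0.5))
  expect_equal(mean(w), 0)
  expect_equal(sd(w), 1)
  tcs_w <- make_tcs(list(A = cbind(p1 = w, p2 = w)))
  expect_equal(detect_extremes(tcs_w, "c1", "peak")$indices, integer(0))
  expect_equal(detect_extremes(tcs_w, "c1", "trough")$indices, integer(0))

  expect_equal(detect_extremes(tcs, "c1", "peak", threshold = Inf)$indices,
               integer(0))
  const <- make_tcs(list(A = cbind(p1 = rep(1, 5), p2 = rep(1, 5))))
  expect_error(detect_extremes(const, "c1", "peak"), "constant")
  expect_error(detect_extremes(tcs, "nope", "peak"), "unknown condition")
})

test_that("polarity symmetry: peaks of -x are troughs of x", {
  set.seed(77)
  m <- rand_mat(60, 5, 77)
  tcs_pos <- make_tcs(list(A = m))
  tcs_neg <- make_tcs(list(A = -m))
  pk <- detect_extremes(tcs_neg, "c1", "peak")
  tr <- detect_extremes(tcs_pos, "c1", "trough")
  expect_equal(pk$indices, tr$indices)
})

test_that("removed_isc deletes the same points everywhere and matches the oracle", {
  set.seed(15)
  mats <- list(A = rand_mat(20, 3, 15), B = rand_mat(20, 3, 16))
  tcs <- make_tcs(mats)

  # empty removal reproduces the plain table
  expect_equal(removed_isc(tcs, "c1", integer(0)), compute_isc_table(tcs))

  idx <- c(3L, 7L, 18L)
  got <- removed_isc(tcs, "c1", idx)
  for (froi in c("A", "B")) {
    kept <- mats[[froi]][-idx, ]
    expect_equal(got$r[got$froi == froi], unname(oracle_loo_isc(kept)),
                 tolerance = 1e-12)
  }

  # boundary: removal down to 3 samples still runs
  small <- make_tcs(list(A = rand_mat(6, 3, 9)))
  left3 <- removed_isc(small, "c1", 1:3)
  expect_equal(left3$n_timepoints, rep(3L, 3))
  expect_error(removed_isc(small, "c1", 1:4), "fewer than 3")
  expect_error(removed_isc(small, "c1", 99), "outside")
})

test_that("random removal null is seeded, sized, and degenerate at m = 0", {
  set.seed(22)
  tcs <- make_tcs(list(A = rand_mat(40, 4, 22)))
  n0 <- random_removal_null(tcs, "c1", m = 0, n_iter = 50, seed = 5)
  base <- mean(compute_isc_table(tcs)$z)
  expect_true(all(abs(n0$values - base) < 1e-12))
  expect_equal(null_pvalue(n0, base), 1)  # add-one rule: (1+n)/(1+n)

  n1 <- random_removal_null(tcs, "c1", m = 5, n_iter = 100, seed = 5)
  n2 <- random_removal_null(tcs, "c1", m = 5, n_iter = 100, seed = 5)
  expect_identical(n1$values, n2$values)
  n3 <- random_removal_null(tcs, "c1", m = 5, n_iter = 100, seed = 6)
  expect_false(identical(n1$values, n3$values))
  expect_length(n1$values, 100)
  expect_error(random_removal_null(tcs, "c1", m = 40, n_iter = 5), "m must")
})

test_that("random removal lowers the mean correlation with m, in expectation", {
  # on the r scale, shortening stationary shared-signal series shrinks the
  # expected sample correlation toward zero, so the removal null's mean
  # decreases with m. (On the Fisher-z scale atanh's convexity can offset
  # this; the distributional location comparison is therefore done on r.)
  diffs <- sapply(1:10, function(seed) {
    d <- make_design("small", seed = seed,
                     tracking_strength = c("+M/+L" = .3, "+M/-L" = .3, "-M/-L" = .3))
    tcs <- preprocess_timecourses(simulate_timecourses(d))
    n_t <- nrow(tcs$series$MiniFilm[[1]])
    mean_r <- sapply(c(2, 30), function(m) {
      set.seed(seed * 100 + m)
      mean(sapply(1:200, function(i) {
        mean(removed_isc(tcs, "MiniFilm", sample(n_t, m))$r)
      }))
    })
    diff(mean_r)
  })
  expect_lt(mean(diffs), 0)
})

test_that("peak removal hurts ISC when shared signal sits in the peaks", {
  tcs <- preprocess_timecourses(simulate_bursts(seed = 42))
  pk <- detect_extremes(tcs, "bursty", "peak")
  expect_gt(length(pk$indices), 0)
  full <- mean(removed_isc(tcs, "bursty", integer(0))$z)
  peak_removed <- mean(removed_isc(tcs, "bursty", pk$indices)$z)
  expect_lt(peak_removed, full)
})

test_that("peak vs trough two-sample test uses pooled df and detects nothing on identical tables", {
  set.seed(55)
  tab <- compute_isc_table(make_tcs(list(A = rand_mat(30, 5, 55))))
  same <- peak_vs_trough_test(tab, tab)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # g observations per group -> df = 2 g - 2 (170 per group gives 338)
  tabA <- data.frame(z = rnorm(170))
  tabB <- data.frame(z = rnorm(170))
  expect_equal(peak_vs_trough_test(tabA, tabB)$df, 338)
  expect_error(peak_vs_trough_test(data.frame(z = 1), tabB), ">= 2")
})

test_that("the full peak/trough analysis returns matched removals and FDR columns", {
  tcs <- preprocess_timecourses(simulate_bursts(seed = 3))
  out <- peak_trough_analysis(tcs, n_iter = 200, seed = 3)
  expect_equal(nrow(out), 1)
  expect_true(all(c("p_fdr_peak_vs_null", "p_fdr_peak_vs_trough") %in% names(out)))
  expect_lt(out$mean_z_peak_removed, out$mean_z)
  expect_lt(out$p_peak_vs_null, 0.05)
})
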