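test_that("z-normalization has mean 0, population variance 1", {
  expect_equal(as.numeric(znormalize(c(1, 2, 3))),
               c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-9)
  x <- rnorm(16, 90, 4)
  z <- znormalize(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(mean(z^2), 1, tolerance = 1e-9)
  # affine invariance for a > 0
  expect_equal(as.numeric(znormalize(2.5 * x + 7)), as.numeric(z),
               tolerance = 1e-9)
  # degenerate constant series is flagged, not an exception
  zc <- znormalize(rep(5, 8))
  expect_true(isTRUE(attr(zc, "degenerate")))
  expect_equal(as.numeric(zc), rep(0, 8))
  expect_error(znormalize(1), "length")
})

test_that("dtw distance matches hand-computed DP values and properties", {
  expect_equal(dtw_distance(c(0, 1, 2), c(0, 2)), 1)
  x <- c(3, 1, 4, 1, 5)
  expect_equal(dtw_distance(x, x), 0)
  y <- c(2, 7, 1, 8, 3)
  expect_equal(dtw_distance(x, y), dtw_distance(y, x))
  expect_lte(dtw_distance(x, y), sum(abs(x - y)))  # identity path feasible
  expect_gte(dtw_distance(x, y), 0)
  expect_error(dtw_distance(numeric(0), y), "empty")
})

test_that("dtw equals the brute-force recursion on an exhaustive universe", {
  # all pairs of length-1..3 series over {0,1,2}, plus random longer pairs
  short <- unlist(lapply(1:3, series_universe), recursive = FALSE)
  for (a in short[seq(1, length(short), by = 4)])
    for (b in short[seq(2, length(short), by = 5)])
      expect_equal(dtw_distance(a, b), dtw_bruteforce(a, b))
  set.seed(14)
  for (rep in 1:200) {
    a <- sample(0:2, sample(4:6, 1), replace = TRUE)
    b <- sample(0:2, sample(4:6, 1), replace = TRUE)
    expect_equal(dtw_distance(a, b), dtw_bruteforce(a, b))
  }
})

test_that("noise-free archetype families are recovered exactly", {
  # 20 copies per archetype of the pure shape around distinct baselines
  cfg <- noiseless_config(n_users = 100, seed = 61)
  ch <- generate_cohort(cfg)
  model <- fit_trajectory_clusters(weight_series_matrix(ch$logs), k = 5,
                                   seed = 8)
  expect_setequal(model$labels, c("sharp decrease", "moderate decrease",
                                  "yo-yo", "increase", "other"))
  agree <- mean(model$assignments == ch$archetype_labels)
  expect_equal(agree, 1)
  if (requireNamespace("mclust", quietly = TRUE))
    expect_equal(mclust::adjustedRandIndex(model$assignments,
                                           ch$archetype_labels), 1)
})

test_that("k = 1 degenerates to a single shared label", {
  ch <- generate_cohort(generator_config(n_users = 20, seed = 5))
  model <- fit_trajectory_clusters(weight_series_matrix(ch$logs), k = 1,
                                   seed = 2, n_init = 1)
  expect_equal(length(unique(model$assignments)), 1)
})

test_that("clustering is deterministic and labels partition the input", {
  ch <- generate_cohort(generator_config(n_users = 60, seed = 19))
  ser <- weight_series_matrix(ch$logs)
  m1 <- fit_trajectory_clusters(ser, k = 5, seed = 4, n_init = 2)
  m2 <- fit_trajectory_clusters(ser, k = 5, seed = 4, n_init = 2)
  expect_identical(m1$barycenters, m2$barycenters)
  expect_identical(m1$assignments, m2$assignments)
  expect_equal(length(m1$assignments), nrow(ser))
  expect_false(any(is.na(m1$assignments)))
  expect_equal(sort(unique(m1$labels)), sort(m1$labels))  # bijection
})

test_that("prefix assignment is consistent, defined from week 2, degenerate-safe", {
  fx <- quick_fit_fixture()
  model <- fx$traj
  ser <- weight_series_matrix(fx$cohort$logs)
  # full series reproduces the training assignment
  for (i in c(1, 10, 40))
    expect_equal(assign_prefix(ser[i, ], model), model$assignments[i])
  # week-1 prefix is reserved
  expect_equal(assign_prefix(ser[1, 1], model), "unassigned")
  # constant prefix routes to the degenerate label
  expect_equal(assign_prefix(rep(90, 6), model), "other")
  # noise-free sharp-decrease prefix at week 8 finds its archetype
  curve <- 90 + retainwl:::archetype_offset("sharp decrease", -11.2, 1:8)
  expect_equal(assign_prefix(curve, model), "sharp decrease")
  # every (user, week >= 2) cell gets exactly one label
  lab <- fx$labels
  expect_true(all(lab[, 1] == "unassigned"))
  expect_true(all(lab[, 2:16] %in% c("sharp decrease", "moderate decrease",
                                     "yo-yo", "increase", "other")))
})
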