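test_that("fixed-feature encoding follows the documented order", {
  prof <- data.frame(user_id = "u1", gender = "female", age = 43.2,
                     height_cm = 166.4, initial_weight_kg = 93.4,
                     target_weight_kg = 85, stringsAsFactors = FALSE)
  F <- encode_fixed(prof)
  expect_equal(colnames(F), c("female", "male", "age", "height",
                              "initial_weight", "overweight", "obese_I",
                              "obese_II", "obese_III"))
  expect_equal(as.vector(F), c(1, 0, 43.2, 166.4, 93.4, 0, 1, 0, 0))
  prof2 <- data.frame(user_id = "u2", gender = "male", age = 50,
                      height_cm = 180, initial_weight_kg = 26 * 1.8^2,
                      target_weight_kg = 80, stringsAsFactors = FALSE)
  F2 <- encode_fixed(prof2)
  expect_equal(as.vector(F2[, c("male", "overweight")]), c(1, 1))
  # encoding is decodable: indicators recover the categorical fields
  expect_equal(unname(F[, "female"] > F[, "male"]), TRUE)
  expect_equal(sum(F[, 6:9]), 1)
})

test_that("tensor emits 16 prefix samples per user sharing the target", {
  fx <- quick_fit_fixture()
  tens <- build_feature_tensor(fx$cohort$logs, fx$cohort$profiles, fx$labels)
  n <- nrow(fx$cohort$profiles)
  expect_equal(dim(tens$X), c(16 * n, 16, 12))
  expect_equal(ncol(tens$F), 9)
  u1 <- tens$sample_index$user_id == fx$cohort$profiles$user_id[1]
  expect_equal(sum(u1), 16)
  expect_equal(length(unique(tens$y[u1])), 1)
  w16 <- fx$cohort$logs$weight_kg[fx$cohort$logs$week == 16 &
    fx$cohort$logs$user_id == fx$cohort$profiles$user_id[1]]
  expect_equal(unique(tens$y[u1]), w16)
  # prefix mask: sample at week 5 sees weeks 1-5 only
  s5 <- which(u1)[5]
  expect_equal(tens$sample_index$prefix_week[s5], 5)
  expect_equal(as.vector(tens$mask[s5, ]), c(rep(1, 5), rep(0, 11)))
  # cluster indicators: at most one per (sample, week); week 1 all zero
  ind <- tens$X[, , 8:12]
  expect_true(all(apply(ind, c(1, 2), sum) <= 1))
  expect_true(all(ind[, 1, ] == 0))
  # exactly one gender indicator
  expect_true(all(tens$F[, "female"] + tens$F[, "male"] == 1))
})

test_that("scaler standardizes unmasked training entries and is leakage-free", {
  fx <- quick_fit_fixture()
  tr <- fx$train
  obs <- tr$mask == 1
  for (v in c("calorie_intake", "steps_k")) {
    vals <- tr$X[, , v][obs]
    expect_lt(abs(mean(vals)), 1e-6)
    expect_equal(sd(vals), 1, tolerance = 1e-6)
  }
  # indicators untouched by scaling
  expect_true(all(tr$X[, , "traj_yoyo"] %in% c(0, 1)))
  # masked entries are exactly zero after standardization
  expect_true(all(tr$X[, , "calorie_intake"][tr$mask == 0] == 0))
  # the scaler was fitted on the training side only: re-fitting on the test
  # side gives different centers
  sc_te_raw <- build_feature_tensor(fx$cohort$logs, fx$cohort$profiles,
                                    fx$labels)
  expect_error(apply_scaler(fx$train, fx$scaler), "already standardized")
})

test_that("user-level split conserves samples and forbids leakage", {
  fx <- quick_fit_fixture()
  tens <- build_feature_tensor(fx$cohort$logs, fx$cohort$profiles, fx$labels)
  sp <- split_dataset(tens, 0.7, seed = 11)
  n <- nrow(fx$cohort$profiles)
  expect_equal(dim(sp$train$X)[1] + dim(sp$test$X)[1], 16 * n)
  tr_u <- unique(sp$train$sample_index$user_id)
  te_u <- unique(sp$test$sample_index$user_id)
  expect_length(intersect(tr_u, te_u), 0)
  expect_equal(length(tr_u), round(0.7 * n))
  # deterministic
  sp2 <- split_dataset(tens, 0.7, seed = 11)
  expect_identical(sp$train$sample_index, sp2$train$sample_index)
  expect_error(split_dataset(tens, 1.2), "in \\(0, 1\\)")
})

test_that("10 users at fraction 0.7 split 7 / 3", {
  ch <- generate_cohort(generator_config(n_users = 10, seed = 8))
  ser <- weight_series_matrix(ch$logs)
  fx <- quick_fit_fixture()
  lab <- assign_trajectories(ser, fx$traj)
  tens <- build_feature_tensor(ch$logs, ch$profiles, lab)
  sp <- split_dataset(tens, 0.7, seed = 2)
  expect_equal(length(unique(sp$train$sample_index$user_id)), 7)
  expect_equal(length(unique(sp$test$sample_index$user_id)), 3)
})

test_that("ablated tensor drops the five cluster-indicator columns", {
  fx <- quick_fit_fixture()
  tens <- build_feature_tensor(fx$cohort$logs, fx$cohort$profiles,
                               traj_labels = NULL,
                               include_trajectories = FALSE)
  expect_equal(dim(tens$X)[3], 7)
  expect_equal(tens$vars, retainwl:::BEHAVIOR_VARS)
})
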