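test_that("decomposition reproduces the forward pass exactly", {
  fx <- quick_fit_fixture()
  S <- dim(fx$test$X)[1]
  for (s in unique(round(seq(1, S, length.out = 25)))) {
    ct <- decompose_prediction(fx$fit, fx$test, s)
    total <- sum(ct$variant$contribution) + sum(ct$fixed$contribution)
    expect_lt(abs(ct$y_std - (total + ct$bias)), 1e-5)
    # kg-scale view decomposes identically
    total_kg <- ct$y_scale * total
    expect_lt(abs(ct$y_kg - (total_kg + ct$bias_kg)), 1e-5)
    # masked weeks contribute nothing
    pw <- fx$test$sample_index$prefix_week[s]
    masked <- ct$variant$week > pw
    expect_true(all(ct$variant$contribution[masked] == 0))
  }
})

test_that("coefficient identity holds exactly cell by cell", {
  fx <- quick_fit_fixture()
  ct <- decompose_prediction(fx$fit, fx$test, 16)
  expect_equal(ct$variant$coefficient,
               ct$variant$alpha * ct$variant$beta * ct$variant$w,
               tolerance = 0)
  expect_equal(ct$variant$contribution,
               ct$variant$coefficient * ct$variant$x, tolerance = 0)
  # zero input zeroes the contribution regardless of the coefficient
  z <- ct$variant$x == 0
  expect_true(all(ct$variant$contribution[z] == 0))
  # fixed variables: coefficient is the output weight itself
  expect_equal(ct$fixed$coefficient, ct$fixed$w)
})

test_that("uniform-attention arithmetic reproduces the reference weightings", {
  # with alpha = 1/16 and saturated |beta| = 1, |coefficient| = |w| / 16:
  # reference output-weight magnitudes against their published coefficient
  # counterparts (printed to 2-3 decimals)
  w <- c(0.340, 0.248, 1.597, 1.066)
  printed <- c(0.021, 0.0155, 0.098, 0.066)
  expect_true(all(abs(w * 0.0625 - printed) < 0.0025))
  # and the model realizes that arithmetic: uniform alpha times beta times w
  p <- uniform_attention_params()
  X <- array(1, c(1, 16, 12))
  fw <- retain_forward(p, X, matrix(0, 1, 9), matrix(1, 1, 16))
  coef <- fw$alpha[1, 3] * fw$beta[1, 3, 2] * p$w_out[2]
  expect_equal(coef, 0.0625 * fw$beta[1, 3, 2] * p$w_out[2])
})

test_that("global pattern of one sample equals that sample's table", {
  fx <- quick_fit_fixture()
  s <- which(fx$test$sample_index$prefix_week == 16)[1]
  one <- subset_tensor(fx$test, s)
  gp <- global_pattern(fx$fit, one)
  ct <- decompose_prediction(fx$fit, fx$test, s)
  expect_equal(gp$n_samples, 1)
  expect_equal(gp$mean_alpha, ct$variant$alpha[1:16], tolerance = 1e-12)
  expect_equal(as.vector(gp$mean_coefficient),
               ct$variant$coefficient, tolerance = 1e-12)
  expect_equal(sum(gp$mean_alpha), 1, tolerance = 1e-6)
  expect_error(global_pattern(fx$fit, subset_tensor(fx$test, integer(0))),
               "empty")
})

test_that("raw-unit conversion rescales coefficients, not contributions", {
  fx <- quick_fit_fixture()
  ct <- decompose_prediction(fx$fit, fx$test, 16)
  raw <- raw_unit_coefficients(ct, fx$scaler)
  v <- raw$variant$variable == "calorie_intake"
  sc <- fx$scaler$scale[["calorie_intake"]]
  expect_equal(raw$variant$coefficient_raw[v],
               ct$variant$coefficient[v] / sc, tolerance = 1e-12)
  expect_equal(raw$variant$coefficient_raw[v] * raw$variant$x_raw_centered[v],
               ct$variant$contribution[v], tolerance = 1e-12)
  # identity scaler leaves indicator columns untouched
  ind <- raw$variant$variable == "traj_yoyo"
  expect_equal(raw$variant$coefficient_raw[ind],
               ct$variant$coefficient[ind])
  # doubling a scale halves the raw coefficient
  sc2 <- fx$scaler
  sc2$scale[["calorie_intake"]] <- 2 * sc
  raw2 <- raw_unit_coefficients(ct, sc2)
  expect_equal(raw2$variant$coefficient_raw[v],
               raw$variant$coefficient_raw[v] / 2, tolerance = 1e-12)
})

test_that("decomposition recomputed at a perturbed input sums to the new prediction", {
  fx <- quick_fit_fixture()
  s <- which(fx$test$sample_index$prefix_week == 16)[2]
  pert <- subset_tensor(fx$test, s)
  pert$X[1, 7, 4] <- pert$X[1, 7, 4] + 0.5
  ct <- decompose_prediction(fx$fit, pert, 1)
  total <- sum(ct$variant$contribution) + sum(ct$fixed$contribution)
  expect_lt(abs(ct$y_std - (total + ct$bias)), 1e-5)
})
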