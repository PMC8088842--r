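random_instance <- function(S = 4, T = 6, N = 3, K = 2, H = 3, seed = 1) {
  set.seed(seed)
  p <- retain_init(N, K, H, seed = seed)
  p$dims$T <- T
  X <- array(rnorm(S * T * N), c(S, T, N))
  F <- matrix(rnorm(S * K), S, K)
  pw <- sample(1:T, S, replace = TRUE)
  mask <- outer(pw, seq_len(T), ">=") * 1
  mask[1, ] <- 1  # keep one full-length sample
  list(p = p, X = X, F = F, mask = mask, y = rnorm(S))
}

test_that("equal logits give exactly uniform attention 1/16", {
  p <- uniform_attention_params()
  X <- array(rnorm(2 * 16 * 12), c(2, 16, 12))
  F <- matrix(rnorm(2 * 9), 2, 9)
  mask <- matrix(1, 2, 16)
  fw <- retain_forward(p, X, F, mask)
  expect_equal(as.vector(fw$alpha), rep(1 / 16, 32))
  expect_equal(unique(as.vector(fw$alpha)), 0.0625)
})

test_that("forward pass satisfies the attention contracts", {
  inst <- random_instance(S = 6, seed = 21)
  fw <- retain_forward(inst$p, inst$X, inst$F, inst$mask)
  expect_equal(rowSums(fw$alpha), rep(1, 6), tolerance = 1e-12)
  expect_true(all(fw$alpha >= 0 & fw$alpha <= 1))
  expect_true(all(abs(fw$beta) <= 1))
  # masked weeks carry zero attention
  expect_true(all(fw$alpha[inst$mask == 0] == 0))
  # context identity c = sum_j alpha_j (beta_j * x_j)
  ctx <- matrix(0, 6, 3)
  for (t in 1:6)
    ctx <- ctx + fw$alpha[, t] * (matrix(fw$beta[, t, ], 6, 3) *
                                    matrix(inst$X[, t, ], 6, 3))
  expect_equal(ctx, fw$context, tolerance = 1e-9)
})

test_that("zero variable-level attention reduces to the fixed-only model", {
  inst <- random_instance(seed = 5)
  p <- inst$p
  p$W_beta[] <- 0
  p$b_beta[] <- 0
  fw <- retain_forward(p, inst$X, inst$F, inst$mask)
  N <- p$dims$N
  expect_equal(fw$y_std,
               as.vector(inst$F %*% p$w_out[N + seq_len(p$dims$K)] + p$b_out),
               tolerance = 1e-12)
  expect_true(all(fw$context == 0))
})

test_that("appending masked weeks never changes the prediction", {
  inst <- random_instance(S = 5, seed = 31)
  fw <- retain_forward(inst$p, inst$X, inst$F, inst$mask)
  X2 <- inst$X
  X2[inst$mask == 0] <- 77  # garbage beyond every prefix
  for (n in seq_len(dim(X2)[3])) {
    slab <- X2[, , n]
    slab[inst$mask == 0] <- -33
    X2[, , n] <- slab
  }
  fw2 <- retain_forward(inst$p, X2, inst$F, inst$mask)
  expect_equal(fw2$y_std, fw$y_std, tolerance = 1e-12)
  expect_error(retain_forward(inst$p, inst$X, inst$F,
                              matrix(0, 5, 6)), "all-masked")
})

test_that("analytic gradients match central finite differences", {
  inst <- random_instance(S = 3, T = 4, seed = 77)
  fw <- retain_forward(inst$p, inst$X, inst$F, inst$mask, keep_cache = TRUE)
  res <- fw$y_std - inst$y
  gv <- retainwl:::params_to_vec(
    retainwl:::retain_backward(inst$p, inst$X, inst$F, inst$mask, fw,
                               2 * res / length(res)))
  pv <- retainwl:::params_to_vec(inst$p)
  loss_at <- function(v) {
    pp <- retainwl:::vec_to_params(v, inst$p)
    mean((retain_forward(pp, inst$X, inst$F, inst$mask)$y_std - inst$y)^2)
  }
  eps <- 1e-5
  num <- vapply(seq_along(pv), function(i) {
    up <- pv; up[i] <- up[i] + eps
    dn <- pv; dn[i] <- dn[i] - eps
    (loss_at(up) - loss_at(dn)) / (2 * eps)
  }, numeric(1))
  rel <- abs(num - gv) / pmax(1e-4, abs(num) + abs(gv))
  expect_lt(max(rel), 1e-4)
})

test_that("training is deterministic and batched prediction matches loops", {
  fx <- quick_fit_fixture()
  cfg <- retain_config(epochs = 2, seed = 17)
  f1 <- retain_train(fx$train, cfg)
  f2 <- retain_train(fx$train, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  # batch vs single-sample agreement
  te <- fx$test
  pred <- retain_predict(fx$fit, te)
  idx <- seq_len(min(50, length(pred)))
  single <- vapply(idx, function(i)
    retain_predict(fx$fit, subset_tensor(te, i)), numeric(1))
  expect_equal(single, pred[idx], tolerance = 1e-6)
  expect_true(all(is.finite(pred)))
})

test_that("per-user prediction error tends to shrink as the prefix grows", {
  fx <- cohort500_fixture()
  pred <- retain_predict(fx$fit, fx$test)
  pw <- vapply(1:16, function(t) {
    sel <- fx$test$sample_index$prefix_week == t
    mape(fx$test$y[sel], pred[sel])
  }, numeric(1))
  expect_lt(pw[16], pw[1])
  expect_lt(mean(pw[9:16]), mean(pw[1:8]))
})
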