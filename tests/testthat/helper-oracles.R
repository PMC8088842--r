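# Independent oracles and shared fixtures (computed once per test run).

# Brute-force DTW by plain recursion with memoisation; written directly from
# the Bellman equation, independent of the package's dynamic program.
dtw_bruteforce <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    if (i == 0 || j == 0) return(Inf)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- abs(a[i] - b[j]) + min(rec(i - 1, j - 1), rec(i - 1, j),
                                  rec(i, j - 1))
    memo[[key]] <- val
    val
  }
  rec(length(a), length(b))
}

# All series of a given length over a small value alphabet.
series_universe <- function(len, alphabet = c(0, 1, 2)) {
  grid <- do.call(expand.grid, rep(list(alphabet), len))
  lapply(seq_len(nrow(grid)), function(i) as.numeric(grid[i, ]))
}

# Fixture cache: heavy objects built once and reused across test files.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# Small noisy cohort with a trained model: used for attention-invariant,
# decomposition, and quick interpretation tests.
quick_fit_fixture <- function() {
  fixture("quick_fit", function() {
    cohort <- generate_cohort(generator_config(n_users = 80, seed = 401))
    series <- weight_series_matrix(cohort$logs)
    tmod <- fit_trajectory_clusters(series, k = 5, seed = 402, n_init = 2)
    labels <- assign_trajectories(series, tmod)
    tensor <- build_feature_tensor(cohort$logs, cohort$profiles, labels)
    sp <- split_dataset(tensor, 0.7, seed = 403)
    scaler <- fit_scaler(sp$train)
    train <- apply_scaler(sp$train, scaler)
    test <- apply_scaler(sp$test, scaler)
    fit <- retain_train(train, retain_config(epochs = 5, seed = 404))
    list(cohort = cohort, traj = tmod, labels = labels, scaler = scaler,
         train = train, test = test, fit = fit)
  })
}

# The main study-scale fixture: n = 500 noisy users, full pipeline.
cohort500_fixture <- function() {
  fixture("cohort500", function() {
    cohort <- generate_cohort(generator_config(n_users = 500, seed = 501))
    series <- weight_series_matrix(cohort$logs)
    tmod <- fit_trajectory_clusters(series, k = 5, seed = 502)
    labels <- assign_trajectories(series, tmod)
    tensor <- build_feature_tensor(cohort$logs, cohort$profiles, labels)
    sp <- split_dataset(tensor, 0.7, seed = 503)
    scaler <- fit_scaler(sp$train)
    train <- apply_scaler(sp$train, scaler)
    test <- apply_scaler(sp$test, scaler)
    fit <- retain_train(train, retain_config(epochs = 25, seed = 504))
    list(cohort = cohort, series = series, traj = tmod, labels = labels,
         scaler = scaler, train = train, test = test, fit = fit)
  })
}

# Tiny deterministic params for closed-form attention checks.
uniform_attention_params <- function(N = 12, K = 9, H = 4) {
  p <- retain_init(N, K, hidden_size = H, seed = 99)
  p$w_alpha[] <- 0          # equal logits at every week
  p$b_alpha <- 0
  p
}
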