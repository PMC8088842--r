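# MAPE metric, repeated 70/30 user-level cross-validation, per-week error
# curves, and the trajectory-feature ablation.

#' Mean absolute percentage error
#'
#' @param actual Observed values (> 0).
#' @param predicted Predictions (same length).
#' @return MAPE in percent: 100/n * sum(|a - p| / a).
#' @export
mape <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) < 1)
    stop("actual and predicted must be equal non-zero length", call. = FALSE)
  if (any(actual <= 0)) stop("actual values must be positive", call. = FALSE)
  100 * mean(abs(actual - predicted) / actual)
}

# Fit the full per-replicate pipeline: trajectory model and scaler on the
# training users only, then train and evaluate.
fit_and_evaluate <- function(profiles, logs, train_users, model_config,
                             cluster_k = 5L, include_trajectories = TRUE,
                             cluster_seed = 1L) {
  in_train <- profiles$user_id %in% train_users
  prof_tr <- profiles[in_train, , drop = FALSE]
  prof_te <- profiles[!in_train, , drop = FALSE]
  series <- weight_series_matrix(logs)

  labels <- NULL
  traj_model <- NULL
  if (include_trajectories) {
    traj_model <- fit_trajectory_clusters(
      series[prof_tr$user_id, , drop = FALSE], k = cluster_k,
      seed = cluster_seed)
    labels <- assign_trajectories(series, traj_model)
  }
  tens_tr <- build_feature_tensor(logs[logs$user_id %in% prof_tr$user_id, ],
                                  prof_tr, labels, include_trajectories)
  tens_te <- build_feature_tensor(logs[logs$user_id %in% prof_te$user_id, ],
                                  prof_te, labels, include_trajectories)
  scaler <- fit_scaler(tens_tr)
  tens_tr <- apply_scaler(tens_tr, scaler)
  tens_te <- apply_scaler(tens_te, scaler)
  fit <- retain_train(tens_tr, model_config)
  pred <- retain_predict(fit, tens_te)

  pw <- vapply(seq_len(N_WEEKS), function(t) {
    sel <- tens_te$sample_index$prefix_week == t
    mape(tens_te$y[sel], pred[sel])
  }, numeric(1))
  list(fit = fit, traj_model = traj_model, scaler = scaler,
       test_tensor = tens_te, predictions = pred,
       overall_mape = mape(tens_te$y, pred), per_week_mape = pw,
       n_test_samples = length(pred))
}

#' Repeated 70/30 cross-validation
#'
#' Runs `n_replicates` Monte-Carlo user-level splits (distinct seeds). Each
#' replicate refits everything on its training side only — trajectory
#' clusters, the feature scaler, and the model — then reports overall and
#' per-prefix-week MAPE on its test users.
#'
#' @param profiles,logs Eligible cohort data.
#' @param model_config A [retain_config()].
#' @param n_replicates Number of replicate splits (default 5).
#' @param train_fraction Training share of users (default 0.7).
#' @param cluster_k Number of trajectory clusters.
#' @param include_trajectories Include trajectory-cluster features.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return An `eval_report`: `overall_mape` (sample-weighted across
#'   replicates), `per_week_mape` (replicates x 16 matrix), `per_fold`
#'   (list of per-replicate summaries), `seeds`, `fingerprint`.
#' @export
cross_validate <- function(profiles, logs, model_config = retain_config(),
                           n_replicates = 5L, train_fraction = 0.7,
                           cluster_k = 5L, include_trajectories = TRUE,
                           seed = 1L) {
  if (length(unique(profiles$user_id)) < 10)
    stop("need at least 10 users for cross-validation", call. = FALSE)
  users <- profiles$user_id
  n_train <- max(1L, min(length(users) - 1L,
                         round(train_fraction * length(users))))
  per_fold <- vector("list", n_replicates)
  pw <- matrix(NA_real_, n_replicates, N_WEEKS)
  seeds <- seed + seq_len(n_replicates)
  for (r in seq_len(n_replicates)) {
    train_users <- with_local_seed(seeds[r], sample(users, n_train))
    cfg <- model_config
    cfg$seed <- as.integer(seeds[r])
    res <- fit_and_evaluate(profiles, logs, train_users, cfg,
                            cluster_k = cluster_k,
                            include_trajectories = include_trajectories,
                            cluster_seed = seeds[r])
    pw[r, ] <- res$per_week_mape
    per_fold[[r]] <- list(seed = seeds[r], overall_mape = res$overall_mape,
                          per_week_mape = res$per_week_mape,
                          n_test_samples = res$n_test_samples,
                          train_users = sort(train_users))
  }
  n_te <- vapply(per_fold, `[[`, numeric(1), "n_test_samples")
  ov <- vapply(per_fold, `[[`, numeric(1), "overall_mape")
  structure(list(overall_mape = sum(ov * n_te) / sum(n_te),
                 per_week_mape = pw, per_fold = per_fold, seeds = seeds,
                 fingerprint = config_fingerprint(
                   list(model = unclass(model_config),
                        n_replicates = n_replicates,
                        train_fraction = train_fraction,
                        cluster_k = cluster_k,
                        include_trajectories = include_trajectories,
                        seed = seed))),
            class = "eval_report")
}

config_fingerprint <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "")
  # small rolling-polynomial digest; stable across sessions
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("cfg-%d", h)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Cross-validation: %d replicates | overall MAPE %.2f%%\n",
              length(x$per_fold), x$overall_mape))
  for (r in seq_along(x$per_fold))
    cat(sprintf("  replicate %d (seed %d): overall %.2f%% | week1 %.2f%% -> week16 %.2f%%\n",
                r, x$per_fold[[r]]$seed, x$per_fold[[r]]$overall_mape,
                x$per_week_mape[r, 1], x$per_week_mape[r, N_WEEKS]))
  invisible(x)
}

#' Write an evaluation report (JSON + human-readable summary)
#'
#' @param report An `eval_report`.
#' @param path Output JSON path; a `.txt` summary is written alongside.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(
    list(overall_mape = report$overall_mape,
         per_week_mape = report$per_week_mape,
         seeds = report$seeds, fingerprint = report$fingerprint,
         per_fold = lapply(report$per_fold, function(f)
           f[c("seed", "overall_mape", "per_week_mape", "n_test_samples")])),
    path, auto_unbox = TRUE, digits = NA)
  txt <- sub("\\.json$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  con <- file(txt, "w"); on.exit(close(con))
  sink(con); print(report); sink()
  invisible(path)
}

#' Trajectory-feature ablation
#'
#' Trains the model twice on the same user split and config: once with the
#' 5 trajectory-cluster indicator columns (N = 12) and once without (N = 7),
#' and reports the paired MAPEs.
#'
#' @param profiles,logs Eligible cohort data.
#' @param model_config A [retain_config()].
#' @param train_fraction Training share of users.
#' @param cluster_k Number of trajectory clusters for the full arm.
#' @param seed Split seed (shared by both arms).
#' @return List with `with_trajectories`, `without_trajectories` (each
#'   carrying overall and per-week MAPE), and `delta_mape` (with - without,
#'   percentage points).
#' @export
ablation_no_trajectory <- function(profiles, logs,
                                   model_config = retain_config(),
                                   train_fraction = 0.7, cluster_k = 5L,
                                   seed = 1L) {
  users <- profiles$user_id
  n_train <- max(1L, min(length(users) - 1L,
                         round(train_fraction * length(users))))
  train_users <- with_local_seed(seed, sample(users, n_train))
  cfg <- model_config
  cfg$seed <- as.integer(seed)
  full <- fit_and_evaluate(profiles, logs, train_users, cfg,
                           cluster_k = cluster_k,
                           include_trajectories = TRUE, cluster_seed = seed)
  ablat <- fit_and_evaluate(profiles, logs, train_users, cfg,
                            include_trajectories = FALSE, cluster_seed = seed)
  list(with_trajectories = full[c("overall_mape", "per_week_mape")],
       without_trajectories = ablat[c("overall_mape", "per_week_mape")],
       delta_mape = full$overall_mape - ablat$overall_mape,
       n_variant_with = dim(full$test_tensor$X)[3],
       n_variant_without = dim(ablat$test_tensor$X)[3],
       seed = seed)
}
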