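# Assembly of the model-ready (sample, week, variable) array, the
# time-fixed matrix, prefix masks, and the fixed week-16 target.

FIXED_VARS <- c("female", "male", "age", "height", "initial_weight",
                "overweight", "obese_I", "obese_II", "obese_III")
FIXED_CONTINUOUS <- c("age", "height", "initial_weight")
TRAJ_VARS <- c("traj_sharp_decrease", "traj_moderate_decrease", "traj_yoyo",
               "traj_increase", "traj_other")

traj_indicator <- function(labels) {
  # labels: character vector; "unassigned" -> all-zero row
  out <- matrix(0, length(labels), 5, dimnames = list(NULL, TRAJ_VARS))
  map <- c("sharp decrease" = 1L, "moderate decrease" = 2L, "yo-yo" = 3L,
           "increase" = 4L, "other" = 5L)
  hit <- !is.na(map[labels])
  out[cbind(which(hit), map[labels[hit]])] <- 1
  out
}

#' Encode time-fixed profile features
#'
#' Fixed order: female, male, age, height, initial weight, then the four
#' obesity-class indicators (overweight, obese I-III). Exactly one gender
#' indicator is 1; at most one obesity-class indicator is 1.
#'
#' @param profiles Eligible profile data frame (with `bmi` present or
#'   derivable from weight/height).
#' @return Numeric matrix (users x 9) with rownames = user ids.
#' @export
encode_fixed <- function(profiles) {
  bmi <- profiles$bmi %||%
    compute_bmi(profiles$initial_weight_kg, profiles$height_cm)
  if (anyNA(bmi) || anyNA(profiles$age))
    stop("profiles contain missing fields", call. = FALSE)
  oc <- obesity_class(bmi)
  F <- cbind(female = as.numeric(profiles$gender == "female"),
             male = as.numeric(profiles$gender == "male"),
             age = profiles$age,
             height = profiles$height_cm,
             initial_weight = profiles$initial_weight_kg,
             overweight = as.numeric(oc == "overweight" & !is.na(oc)),
             obese_I = as.numeric(oc == "obese I" & !is.na(oc)),
             obese_II = as.numeric(oc == "obese II" & !is.na(oc)),
             obese_III = as.numeric(oc == "obese III" & !is.na(oc)))
  rownames(F) <- profiles$user_id
  F
}

#' Build the prefix-sample feature tensor
#'
#' For every eligible user, emits 16 prefix samples: sample (u, t) exposes
#' weeks 1..t (prefix mask) and is masked beyond, and all 16 samples share
#' the same target, the user's week-16 weight. Time-variant variables are the
#' 7 weekly behaviors plus (optionally) 5 one-hot trajectory-cluster
#' indicators, where the indicator at week j reflects the cluster assigned
#' from the prefix 1..j (week 1 is unassigned, all zeros).
#'
#' Values are left in raw units; fit a scaler on the training split with
#' [fit_scaler()] and apply it with [apply_scaler()].
#'
#' @param logs Complete 16-week log data frame.
#' @param profiles Eligible profile data frame.
#' @param traj_labels Character matrix (users x 16) from
#'   [assign_trajectories()], or `NULL` with `include_trajectories = FALSE`.
#' @param include_trajectories Include the 5 cluster-indicator columns
#'   (`FALSE` gives the 7-variable ablated tensor).
#' @return A `feature_tensor`: `X` (samples x 16 x N), `F` (samples x 9),
#'   `mask` (samples x 16), `y` (week-16 weight, kg), `sample_index`
#'   (user_id, prefix_week), `vars`, `scaler` (NULL until standardized).
#' @export
build_feature_tensor <- function(logs, profiles, traj_labels = NULL,
                                 include_trajectories = TRUE) {
  users <- profiles$user_id
  n <- length(users)
  if (include_trajectories) {
    if (is.null(traj_labels)) stop("traj_labels required", call. = FALSE)
    if (!all(users %in% rownames(traj_labels)))
      stop("unknown user in trajectory labels", call. = FALSE)
  }
  vars <- if (include_trajectories) c(BEHAVIOR_VARS, TRAJ_VARS) else
    BEHAVIOR_VARS
  N <- length(vars)

  # user-level (n x 16 x N) array
  Xu <- array(0, c(n, N_WEEKS, N), dimnames = list(users, NULL, vars))
  ord <- order(match(logs$user_id, users), logs$week)
  lg <- logs[ord, , drop = FALSE]
  if (nrow(lg) != n * N_WEEKS)
    stop("logs must contain exactly 16 weeks per profile user", call. = FALSE)
  for (v in BEHAVIOR_VARS)
    Xu[, , v] <- matrix(lg[[v]], n, N_WEEKS, byrow = TRUE)
  if (include_trajectories) {
    lab <- traj_labels[users, , drop = FALSE]
    for (t in seq_len(N_WEEKS))
      Xu[, t, TRAJ_VARS] <- traj_indicator(lab[, t])
  }
  wkg <- matrix(lg$weight_kg, n, N_WEEKS, byrow = TRUE)
  y_user <- wkg[, N_WEEKS]

  Fu <- encode_fixed(profiles)

  # expand to 16 prefix samples per user
  S <- n * N_WEEKS
  u_idx <- rep(seq_len(n), each = N_WEEKS)
  t_idx <- rep(seq_len(N_WEEKS), n)
  X <- Xu[u_idx, , , drop = FALSE]
  F <- Fu[u_idx, , drop = FALSE]
  mask <- outer(t_idx, seq_len(N_WEEKS), ">=") * 1
  y <- y_user[u_idx]
  sample_index <- data.frame(user_id = users[u_idx], prefix_week = t_idx,
                             stringsAsFactors = FALSE)
  structure(list(X = X, F = F, mask = mask, y = y,
                 sample_index = sample_index, vars = vars,
                 fixed_vars = FIXED_VARS, scaler = NULL),
            class = "feature_tensor")
}

#' @export
print.feature_tensor <- function(x, ...) {
  cat("Feature tensor:", dim(x$X)[1], "samples x", dim(x$X)[2], "weeks x",
      dim(x$X)[3], "time-variant variables;",
      ncol(x$F), "time-fixed features",
      if (!is.null(x$scaler)) "(standardized)" else "(raw units)", "\n")
  invisible(x)
}

#' Fit a standardization scaler on a training tensor
#'
#' Continuous behavior columns are centered/scaled over the unmasked
#' (sample, week) entries; age, height and initial weight over samples;
#' the target over samples. Indicator columns are untouched (scale 1,
#' center 0).
#'
#' @param tensor A raw-unit `feature_tensor` (training split only).
#' @return A `retain_scaler` list with per-variable centers and scales.
#' @export
fit_scaler <- function(tensor) {
  stopifnot(inherits(tensor, "feature_tensor"))
  vars <- tensor$vars
  center <- stats::setNames(rep(0, length(vars)), vars)
  scale <- stats::setNames(rep(1, length(vars)), vars)
  obs <- tensor$mask == 1
  for (v in intersect(vars, BEHAVIOR_VARS)) {
    vals <- tensor$X[, , v][obs]
    center[v] <- mean(vals)
    s <- stats::sd(vals)
    scale[v] <- if (is.finite(s) && s > 1e-12) s else 1
  }
  fcenter <- stats::setNames(rep(0, length(FIXED_VARS)), FIXED_VARS)
  fscale <- stats::setNames(rep(1, length(FIXED_VARS)), FIXED_VARS)
  for (v in FIXED_CONTINUOUS) {
    fcenter[v] <- mean(tensor$F[, v])
    s <- stats::sd(tensor$F[, v])
    fscale[v] <- if (is.finite(s) && s > 1e-12) s else 1
  }
  y_center <- mean(tensor$y)
  y_scale <- stats::sd(tensor$y)
  if (!is.finite(y_scale) || y_scale < 1e-12) y_scale <- 1
  structure(list(center = center, scale = scale,
                 fixed_center = fcenter, fixed_scale = fscale,
                 y_center = y_center, y_scale = y_scale),
            class = "retain_scaler")
}

#' Apply (or re-apply) a fitted scaler to a tensor
#'
#' @param tensor A raw-unit `feature_tensor`.
#' @param scaler A `retain_scaler` from [fit_scaler()].
#' @return Standardized `feature_tensor` (with `scaler` attached; `y` is kept
#'   in kg, the model standardizes the target internally via the scaler).
#' @export
apply_scaler <- function(tensor, scaler) {
  stopifnot(inherits(tensor, "feature_tensor"),
            inherits(scaler, "retain_scaler"))
  if (!is.null(tensor$scaler)) stop("tensor already standardized",
                                    call. = FALSE)
  for (v in tensor$vars)
    tensor$X[, , v] <- (tensor$X[, , v] - scaler$center[v]) / scaler$scale[v]
  # masked entries stay exactly zero so padding never leaks into the model
  tensor$X <- tensor$X * as.vector(tensor$mask)
  for (v in colnames(tensor$F))
    tensor$F[, v] <- (tensor$F[, v] - scaler$fixed_center[v]) /
      scaler$fixed_scale[v]
  tensor$scaler <- scaler
  tensor
}

#' Split a tensor by user
#'
#' All 16 prefix samples of a user land on the same side (leakage guard).
#'
#' @param tensor A `feature_tensor`.
#' @param train_fraction Fraction of users in the training split.
#' @param seed Integer seed (reproducible split).
#' @return List with `train` and `test` feature tensors.
#' @export
split_dataset <- function(tensor, train_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(tensor, "feature_tensor"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  users <- unique(tensor$sample_index$user_id)
  if (length(users) < 2) stop("need at least 2 users", call. = FALSE)
  n_train <- max(1L, min(length(users) - 1L,
                         round(train_fraction * length(users))))
  train_users <- with_local_seed(seed, sample(users, n_train))
  list(train = subset_tensor(tensor,
                             tensor$sample_index$user_id %in% train_users),
       test = subset_tensor(tensor,
                            !tensor$sample_index$user_id %in% train_users))
}

#' Subset a feature tensor by sample
#'
#' @param tensor A `feature_tensor`.
#' @param idx Logical or integer sample index.
#' @return The subset `feature_tensor`.
#' @export
subset_tensor <- function(tensor, idx) {
  tensor$X <- tensor$X[idx, , , drop = FALSE]
  tensor$F <- tensor$F[idx, , drop = FALSE]
  tensor$mask <- tensor$mask[idx, , drop = FALSE]
  tensor$y <- tensor$y[idx]
  tensor$sample_index <- tensor$sample_index[idx, , drop = FALSE]
  tensor
}
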