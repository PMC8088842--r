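# Exact additive decomposition of predictions into per-variable, per-week
# contributions, and test-set-level aggregation of the attention patterns.

#' Decompose one prediction into additive contributions
#'
#' For time-variant variable n at week j the contribution coefficient is
#' alpha_j * beta_jn * w_n and its contribution is that coefficient times
#' the (standardized) input x_jn; for time-fixed variable m the coefficient
#' is its output weight w_m. The contributions plus the bias reproduce the
#' model output exactly (float slack only); masked weeks contribute zero.
#' Coefficients and contributions are on the model (standardized-target)
#' scale, where the output weights live; multiply by `scaler$y_scale` for kg
#' (the table carries both, the kg bias absorbing the target center).
#'
#' @param fit A `retain_fit`.
#' @param tensor A standardized `feature_tensor`.
#' @param sample Single sample index into the tensor.
#' @return A `contribution_table`: `variant` data frame (week, variable,
#'   alpha, beta, w, coefficient, x, contribution), `fixed` data frame
#'   (variable, w, coefficient, x, contribution), `bias`, `y_std`, `y_kg`.
#' @export
decompose_prediction <- function(fit, tensor, sample = 1L) {
  stopifnot(inherits(fit, "retain_fit"), length(sample) == 1L)
  fw <- retain_forward(fit$params, tensor$X[sample, , , drop = FALSE],
                       tensor$F[sample, , drop = FALSE],
                       tensor$mask[sample, , drop = FALSE])
  d <- fit$params$dims
  w_var <- fit$params$w_out[seq_len(d$N)]
  w_fix <- fit$params$w_out[d$N + seq_len(d$K)]
  alpha <- as.vector(fw$alpha)
  beta <- matrix(fw$beta[1, , ], d$T, d$N)
  x <- matrix(tensor$X[sample, , ], d$T, d$N)
  coef <- alpha * beta * rep(w_var, each = d$T)
  contrib <- coef * x
  variant <- data.frame(
    week = rep(seq_len(d$T), d$N),
    variable = rep(fit$vars, each = d$T),
    alpha = rep(alpha, d$N),
    beta = as.vector(beta),
    w = rep(w_var, each = d$T),
    coefficient = as.vector(coef),
    x = as.vector(x),
    contribution = as.vector(contrib),
    stringsAsFactors = FALSE)
  fixed <- data.frame(
    variable = fit$fixed_vars,
    w = w_fix,
    coefficient = w_fix,
    x = as.vector(tensor$F[sample, ]),
    contribution = w_fix * as.vector(tensor$F[sample, ]),
    stringsAsFactors = FALSE)
  ys <- fit$scaler$y_scale
  structure(list(variant = variant, fixed = fixed,
                 bias = fit$params$b_out,
                 bias_kg = fit$params$b_out * ys + fit$scaler$y_center,
                 y_scale = ys,
                 y_std = fw$y_std, y_kg = fw$y_std * ys + fit$scaler$y_center,
                 sample_index = tensor$sample_index[sample, , drop = FALSE]),
            class = "contribution_table")
}

#' @export
print.contribution_table <- function(x, ...) {
  tot <- sum(x$variant$contribution) + sum(x$fixed$contribution)
  cat(sprintf("Contribution table (user %s, prefix week %d)\n",
              x$sample_index$user_id, x$sample_index$prefix_week))
  cat(sprintf("  prediction %.2f kg = bias %.2f + contributions %.4f (model scale)\n",
              x$y_kg, x$bias, tot))
  top <- x$variant[order(-abs(x$variant$contribution)), ][1:5, ]
  cat("  top time-variant contributions:\n")
  for (i in seq_len(nrow(top)))
    cat(sprintf("    wk %2d %-22s %+0.4f\n", top$week[i], top$variable[i],
                top$contribution[i]))
  invisible(x)
}

#' Average attention and coefficient patterns over a test set
#'
#' Averages per-week time-level attention, per-(week, variable)
#' variable-level attention and contribution coefficients, and the fixed
#' variable coefficients, over samples of a test tensor. By default only
#' full-length (prefix week 16) samples enter, matching a 16-week axis; set
#' `full_length_only = FALSE` to average over all prefix samples.
#'
#' @param fit A `retain_fit`.
#' @param tensor A standardized `feature_tensor` (test split).
#' @param full_length_only Restrict to prefix-week-16 samples.
#' @return A `global_pattern`: `mean_alpha` (16), `mean_beta` (16 x N),
#'   `mean_coefficient` (16 x N), `fixed_coefficients` (K), `n_samples`.
#' @export
global_pattern <- function(fit, tensor, full_length_only = TRUE) {
  stopifnot(inherits(fit, "retain_fit"))
  keep <- if (full_length_only)
    which(tensor$sample_index$prefix_week == N_WEEKS)
  else seq_len(dim(tensor$X)[1])
  if (length(keep) == 0) stop("empty test set", call. = FALSE)
  d <- fit$params$dims
  w_var <- fit$params$w_out[seq_len(d$N)]
  sum_alpha <- numeric(d$T)
  sum_beta <- matrix(0, d$T, d$N)
  sum_ab <- matrix(0, d$T, d$N)
  n <- 0L
  for (chunk in split(keep, ceiling(seq_along(keep) / 4096))) {
    fw <- retain_forward(fit$params, tensor$X[chunk, , , drop = FALSE],
                         tensor$F[chunk, , drop = FALSE],
                         tensor$mask[chunk, , drop = FALSE])
    sum_alpha <- sum_alpha + colSums(fw$alpha)
    for (t in seq_len(d$T)) {
      bt <- matrix(fw$beta[, t, ], length(chunk), d$N)
      sum_beta[t, ] <- sum_beta[t, ] + colSums(bt)
      sum_ab[t, ] <- sum_ab[t, ] + colSums(fw$alpha[, t] * bt)
    }
    n <- n + length(chunk)
  }
  mean_coef <- sweep(sum_ab / n, 2, w_var, `*`)
  dimnames(mean_coef) <- list(NULL, fit$vars)
  mb <- sum_beta / n; colnames(mb) <- fit$vars
  structure(list(mean_alpha = sum_alpha / n, mean_beta = mb,
                 mean_coefficient = mean_coef,
                 fixed_coefficients = stats::setNames(
                   fit$params$w_out[d$N + seq_len(d$K)], fit$fixed_vars),
                 n_samples = n),
            class = "global_pattern")
}

#' @export
print.global_pattern <- function(x, ...) {
  cat("Global attention pattern over", x$n_samples, "samples\n")
  cat("mean alpha per week:\n ")
  cat(sprintf(" %.4f", x$mean_alpha), "\n")
  cat("mean contribution coefficient (averaged over weeks):\n")
  print(round(colMeans(x$mean_coefficient), 4))
  cat("fixed-variable coefficients:\n")
  print(round(x$fixed_coefficients, 4))
  invisible(x)
}

#' Write a global pattern as delimited text
#'
#' @param pattern A `global_pattern`.
#' @param path Output CSV path.
#' @export
write_global_pattern <- function(pattern, path) {
  long <- data.frame(
    week = rep(seq_along(pattern$mean_alpha), 1 + 2 * ncol(pattern$mean_beta)),
    quantity = c(rep("alpha", length(pattern$mean_alpha)),
                 rep(paste0("beta.", colnames(pattern$mean_beta)),
                     each = nrow(pattern$mean_beta)),
                 rep(paste0("coefficient.", colnames(pattern$mean_coefficient)),
                     each = nrow(pattern$mean_coefficient))),
    value = c(pattern$mean_alpha, as.vector(pattern$mean_beta),
              as.vector(pattern$mean_coefficient)))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Convert a contribution table to raw-unit coefficients
#'
#' Standardized coefficients are divided by each variable's scaler SD, giving
#' coefficients per raw unit (per n/week, per kcal, ...). Contributions are
#' unchanged: the raw-unit coefficient multiplies the mean-centered raw
#' value, which equals the standardized contribution by construction.
#'
#' @param table A `contribution_table`.
#' @param scaler A `retain_scaler`; defaults to the one inside the table's
#'   fit is not stored, so pass the training scaler.
#' @return The table with `coefficient_raw` and `x_raw_centered` columns
#'   added to its `variant` (and `fixed`) components.
#' @export
raw_unit_coefficients <- function(table, scaler) {
  stopifnot(inherits(table, "contribution_table"),
            inherits(scaler, "retain_scaler"))
  sc <- scaler$scale[table$variant$variable]
  sc[is.na(sc)] <- 1   # indicator columns: scale 1
  table$variant$coefficient_raw <- table$variant$coefficient / sc
  table$variant$x_raw_centered <- table$variant$x * sc
  fsc <- scaler$fixed_scale[table$fixed$variable]
  fsc[is.na(fsc)] <- 1
  table$fixed$coefficient_raw <- table$fixed$coefficient / fsc
  table$fixed$x_raw_centered <- table$fixed$x * fsc
  table
}
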