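# Shape-based clustering of weekly weight series under dynamic time warping.

#' z-normalize a series (population variance)
#'
#' Centers to mean 0 and scales to population variance 1 (division by n, the
#' convention in shape-based series clustering). A constant series cannot be
#' z-normalized: it is returned as all zeros with attribute
#' `degenerate = TRUE`, and downstream assignment routes such series to the
#' "other" cluster.
#'
#' @param x Numeric series of length >= 2.
#' @return z-scored series; possibly with attribute `degenerate`.
#' @export
znormalize <- function(x) {
  if (length(x) < 2) stop("series must have length >= 2", call. = FALSE)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (!is.finite(s) || s < 1e-12)
    return(structure(rep(0, length(x)), degenerate = TRUE))
  (x - m) / s
}

is_degenerate <- function(z) isTRUE(attr(z, "degenerate"))

#' Dynamic time warping distance
#'
#' Classic DTW with absolute-difference local cost and symmetric steps
#' (match, insert, delete), no window constraint.
#'
#' @param a,b Non-empty numeric series (lengths may differ).
#' @return Non-negative warping distance.
#' @export
dtw_distance <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty series", call. = FALSE)
  dtw_dist_cpp(as.numeric(a), as.numeric(b))
}

# Canonical z-normalized shape templates used to map fitted clusters to
# semantic archetype labels (best bijection over all permutations).
canonical_templates <- function(len = N_WEEKS) {
  t <- seq_len(len)
  shapes <- list(
    "sharp decrease"    = -(1 - exp(-t / 2)),
    "moderate decrease" = -t,
    "yo-yo"             = ifelse(t <= len / 2,
                                 -(1 - exp(-t / 3)) / (1 - exp(-len / 6)),
                                 -1 + (t - len / 2) / (len / 2)),
    "increase"          = t,
    "other"             = sin(pi * t / len))   # inverted-U catchall
  lapply(shapes, function(s) as.numeric(znormalize(s)))
}

label_clusters <- function(barycenters) {
  k <- nrow(barycenters)
  tmpl <- canonical_templates(ncol(barycenters))
  cost <- matrix(0, k, length(tmpl))
  for (i in seq_len(k)) {
    z <- znorm_safe(barycenters[i, ])
    for (j in seq_along(tmpl)) cost[i, j] <- dtw_dist_cpp(z, tmpl[[j]])
  }
  if (k == length(tmpl)) {
    perms <- all_permutations(k)
    tot <- apply(perms, 1, function(p) sum(cost[cbind(seq_len(k), p)]))
    p <- perms[which.min(tot), ]
    names(tmpl)[p]
  } else {
    # k != 5: label each cluster by its nearest template (not a bijection)
    names(tmpl)[apply(cost, 1, which.min)]
  }
}

all_permutations <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    block <- cbind(i, ifelse(sub >= i, sub + 1L, sub))
    out <- rbind(out, block)
  }
  out
}

# Center always; scale only if non-constant (used where a truncated
# barycenter segment may be flat).
znorm_safe <- function(x) {
  z <- znormalize(x)
  if (is_degenerate(z)) x - mean(x) else as.numeric(z)
}

# DTW barycenter averaging: align members to the current barycenter and
# average the values mapped onto each barycenter index.
dba_update <- function(series_mat, center, iter = 3L) {
  for (it in seq_len(iter)) {
    sums <- numeric(length(center))
    cnts <- numeric(length(center))
    for (i in seq_len(nrow(series_mat))) {
      p <- dtw_path_cpp(series_mat[i, ], center)
      sums[p[, 2]] <- sums[p[, 2]] + series_mat[i, p[, 1]]
      cnts[p[, 2]] <- cnts[p[, 2]] + 1
    }
    newc <- ifelse(cnts > 0, sums / pmax(cnts, 1), center)
    if (max(abs(newc - center)) < 1e-10) { center <- newc; break }
    center <- newc
  }
  center
}

kmeanspp_init <- function(Z, k) {
  n <- nrow(Z)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- apply(Z, 1, function(x) dtw_dist_cpp(x, Z[centers[1], ]))^2
  for (j in 2:k) {
    if (sum(d2) <= 0) centers[j] <- sample.int(n, 1)
    else centers[j] <- sample.int(n, 1, prob = d2)
    dj <- apply(Z, 1, function(x) dtw_dist_cpp(x, Z[centers[j], ]))^2
    d2 <- pmin(d2, dj)
  }
  centers
}

#' Fit weight-loss trajectory clusters
#'
#' k-means under dynamic time warping on z-normalized weekly weight series,
#' with DTW barycenter averaging for the centroid update and a
#' k-means++-style initialization. Several restarts are run and the solution
#' with the lowest within-cluster DTW inertia is kept; everything is
#' deterministic given `seed`. Fitted clusters are mapped to semantic labels
#' (sharp decrease, moderate decrease, yo-yo, increase, other) by matching
#' their barycenter shapes to canonical templates.
#'
#' @param series Numeric matrix (users x 16 weeks) of raw weight series in
#'   kg, or a list of length-16 numeric vectors. Series are z-normalized
#'   internally.
#' @param k Number of clusters (default 5).
#' @param seed Integer seed.
#' @param n_init Number of restarts.
#' @param max_iter Maximum k-means iterations per restart.
#' @return A `trajectory_model` with `barycenters` (k x 16, z-space),
#'   `labels` (semantic label per cluster), `assignments` (semantic label per
#'   input series), `inertia`, and `fit_seed`.
#' @export
fit_trajectory_clusters <- function(series, k = 5L, seed = 1L,
                                    n_init = 5L, max_iter = 25L) {
  if (is.list(series)) series <- do.call(rbind, series)
  stopifnot(is.matrix(series), ncol(series) >= 2)
  if (nrow(series) < k) stop("fewer series than clusters", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)

  Z <- t(apply(series, 1, znorm_safe))
  degen <- apply(series, 1, function(x) is_degenerate(znormalize(x)))

  run_once <- function(rs, init_centers = NULL) {
    with_local_seed(rs, {
      centers <- if (is.null(init_centers))
        Z[kmeanspp_init(Z, k), , drop = FALSE] else init_centers
      assign_old <- rep(0L, nrow(Z))
      for (it in seq_len(max_iter)) {
        D <- matrix(0, nrow(Z), k)
        for (j in seq_len(k))
          D[, j] <- apply(Z, 1, function(x) dtw_dist_cpp(x, centers[j, ]))
        asg <- apply(D, 1, which.min)   # which.min: lowest index on ties
        for (j in seq_len(k)) {
          if (!any(asg == j)) {         # empty cluster: grab farthest point
            far <- which.max(D[cbind(seq_len(nrow(Z)), asg)])
            asg[far] <- j
          }
        }
        if (all(asg == assign_old)) break
        assign_old <- asg
        for (j in seq_len(k))
          centers[j, ] <- dba_update(Z[asg == j, , drop = FALSE],
                                     centers[j, ])
      }
      inertia <- sum(vapply(seq_len(nrow(Z)), function(i)
        dtw_dist_cpp(Z[i, ], centers[asg[i], ])^2, numeric(1)))
      list(centers = centers, assignments = asg, inertia = inertia)
    })
  }

  best <- NULL
  for (r in seq_len(n_init)) {
    res <- run_once(seed + r - 1L)
    if (is.null(best) || res$inertia < best$inertia) best <- res
  }
  if (k == length(ARCHETYPES)) {
    # additional deterministic run seeded at the canonical shape templates
    # (k-means++ alone is prone to merging the two monotone-decline
    # families into one cluster and splitting another)
    tmpl <- do.call(rbind, canonical_templates(ncol(Z)))
    res <- run_once(seed, init_centers = tmpl)
    if (res$inertia < best$inertia) best <- res
  }

  labels <- label_clusters(best$centers)
  model <- structure(list(k = as.integer(k), barycenters = best$centers,
                          labels = labels, inertia = best$inertia,
                          fit_seed = as.integer(seed)),
                     class = "trajectory_model")
  # Final assignment through the same path prefix assignment uses (full
  # length), guaranteeing consistency between training labels and
  # assign_prefix at t = 16; degenerate series route to "other".
  asg_lab <- vapply(seq_len(nrow(series)), function(i)
    assign_prefix(series[i, ], model), character(1))
  model$assignments <- asg_lab
  model
}

#' @export
print.trajectory_model <- function(x, ...) {
  cat("DTW k-means trajectory model: k =", x$k,
      "| inertia =", signif(x$inertia, 5), "\n")
  cat("cluster labels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Assign a (possibly partial) weight series to a trajectory cluster
#'
#' Real-time assignment: the prefix (weeks 1..t) is z-normalized and compared
#' by DTW to each fitted barycenter truncated to its first t weeks and
#' re-z-normalized. Week-1 prefixes cannot be z-normalized and return the
#' reserved `"unassigned"` code; constant prefixes route to `"other"`.
#'
#' @param prefix Numeric vector of weekly weights, weeks 1..t.
#' @param model A fitted `trajectory_model`.
#' @return A single semantic cluster label (or `"unassigned"`).
#' @export
assign_prefix <- function(prefix, model) {
  stopifnot(inherits(model, "trajectory_model"))
  t <- length(prefix)
  if (t < 2) return("unassigned")
  z <- znormalize(prefix)
  if (is_degenerate(z)) return("other")
  t <- min(t, ncol(model$barycenters))
  d <- vapply(seq_len(model$k), function(j)
    dtw_dist_cpp(as.numeric(z), znorm_safe(model$barycenters[j, 1:t])),
    numeric(1))
  model$labels[which.min(d)]
}

#' Per-user, per-week trajectory labels
#'
#' Applies [assign_prefix()] to every prefix (weeks 1..t, t = 1..16) of every
#' user's weight series.
#'
#' @param series Matrix (users x 16) of weekly weights, rownames = user ids.
#' @param model A fitted `trajectory_model`.
#' @return Character matrix (users x 16) of labels; week 1 is `"unassigned"`.
#' @export
assign_trajectories <- function(series, model) {
  stopifnot(is.matrix(series))
  out <- matrix("unassigned", nrow(series), ncol(series),
                dimnames = dimnames(series))
  for (i in seq_len(nrow(series)))
    for (t in 2:ncol(series))
      out[i, t] <- assign_prefix(series[i, 1:t], model)
  out
}

#' Extract per-user weight series matrix from long-format logs
#'
#' @param logs Weekly log data frame with `user_id`, `week`, `weight_kg`.
#' @return Numeric matrix (users x 16), rownames = user ids.
#' @export
weight_series_matrix <- function(logs) {
  users <- unique(logs$user_id)
  mat <- matrix(NA_real_, length(users), N_WEEKS,
                dimnames = list(users, NULL))
  mat[cbind(match(logs$user_id, users), logs$week)] <-
    logs$weight_kg
  if (anyNA(mat)) stop("incomplete weight series; filter eligibility first",
                       call. = FALSE)
  mat
}
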