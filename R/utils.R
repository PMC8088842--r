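# Internal helpers shared across modules.

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so package functions never clobber user RNG.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Truncated-normal sampling by inverse CDF (exact, reproducible).
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(pmin(pmax(rep_len(mean, n), lower), upper))
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, pl, pu)
  stats::qnorm(u, mean, sd)
}

# Mean of a normal(mean, sd) truncated to [lower, upper].
trunc_norm_mean <- function(mean, sd, lower = -Inf, upper = Inf) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  za <- if (is.finite(a)) stats::dnorm(a) else 0
  zb <- if (is.finite(b)) stats::dnorm(b) else 0
  denom <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (za - zb) / denom
}

# Latent mean such that the [lower, upper]-truncated draw has mean `target`.
calibrate_trunc_mean <- function(target, sd, lower = -Inf, upper = Inf) {
  f <- function(mu) trunc_norm_mean(mu, sd, lower, upper) - target
  stats::uniroot(f, interval = c(target - 6 * sd, target + 6 * sd),
                 tol = 1e-10)$root
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive number", what), call. = FALSE)
}
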