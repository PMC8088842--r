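# Conditional RETAIN regression core: two recurrent attention generators
# over the time-variant inputs (consumed in reverse time), a context vector,
# concatenation with time-fixed features, and a linear output head. The
# forward pass, backpropagation-through-time, and Adam are implemented
# directly with vectorized matrix algebra; gradient correctness is pinned by
# finite-difference tests.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Training configuration for the conditional RETAIN model
#'
#' @param hidden_size GRU hidden units for both attention generators.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size (samples).
#' @param learning_rate Adam step size.
#' @param val_fraction Fraction of training users held out to select the
#'   best-on-validation parameters.
#' @param weight_decay Decoupled L2 decay applied to the recurrent and
#'   attention-projection weights (never to the linear output head, whose
#'   entries are the interpretable coefficients).
#' @param seed Seed controlling initialization and minibatch order.
#' @param reverse_time Feed the sequence to both attention RNNs in reverse
#'   time (the RETAIN convention); `FALSE` uses forward time.
#' @return A `retain_config` list.
#' @export
retain_config <- function(hidden_size = 16L, epochs = 50L,
                          batch_size = 512L, learning_rate = 0.01,
                          weight_decay = 2, val_fraction = 0.1, seed = 1L,
                          reverse_time = TRUE) {
  stopifnot(hidden_size >= 1, epochs >= 1, batch_size >= 1,
            learning_rate > 0, weight_decay >= 0,
            val_fraction >= 0, val_fraction < 1)
  structure(list(hidden_size = as.integer(hidden_size),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 val_fraction = val_fraction, seed = as.integer(seed),
                 reverse_time = isTRUE(reverse_time)),
            class = "retain_config")
}

glorot <- function(nr, nc) {
  a <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -a, a), nr, nc)
}

#' Initialize model parameters
#'
#' @param n_variant Number of time-variant variables N.
#' @param n_fixed Number of time-fixed features K.
#' @param hidden_size GRU hidden size.
#' @param seed Integer seed.
#' @param reverse_time Time direction flag stored with the parameters.
#' @return A `retain_params` list (GRU weights for both generators, the
#'   alpha and beta projections, and the length N + K output weight vector).
#' @export
retain_init <- function(n_variant, n_fixed, hidden_size = 16L, seed = 1L,
                        reverse_time = TRUE) {
  N <- as.integer(n_variant); K <- as.integer(n_fixed)
  H <- as.integer(hidden_size)
  with_local_seed(seed, {
    gru <- function() list(W = glorot(N, 3L * H), U = glorot(H, 3L * H),
                           b = rep(0, 3L * H))
    structure(list(gru_a = gru(), gru_b = gru(),
                   w_alpha = stats::runif(H, -0.1, 0.1), b_alpha = 0,
                   W_beta = glorot(H, N), b_beta = rep(0, N),
                   w_out = stats::runif(N + K, -0.1, 0.1), b_out = 0,
                   dims = list(N = N, K = K, H = H, T = N_WEEKS),
                   reverse_time = isTRUE(reverse_time)),
              class = "retain_params")
  })
}

gru_forward <- function(gru, X, mask, ord, H) {
  S <- dim(X)[1]; T <- dim(X)[2]; N <- dim(X)[3]
  zi <- seq_len(H); ri <- H + zi; ni <- 2L * H + zi
  h <- matrix(0, S, H)
  Hs <- array(0, c(S, T, H))
  cache <- vector("list", T)
  for (s in seq_len(T)) {
    t <- ord[s]
    x <- matrix(X[, t, ], S, N)
    m <- mask[, t]
    xa <- x %*% gru$W + rep(gru$b, each = S)
    hu <- h %*% gru$U[, c(zi, ri)]
    z <- sigmoid(xa[, zi] + hu[, zi])
    r <- sigmoid(xa[, ri] + hu[, ri])
    n <- tanh(xa[, ni] + (r * h) %*% gru$U[, ni])
    hnew <- (1 - z) * n + z * h
    cache[[s]] <- list(h_prev = h, z = z, r = r, n = n, t = t, m = m)
    h <- m * hnew + (1 - m) * h
    Hs[, t, ] <- h
  }
  list(H = Hs, cache = cache)
}

gru_backward <- function(gru, X, cache, dH_inject, H) {
  S <- dim(X)[1]; T <- dim(X)[2]; N <- dim(X)[3]
  zi <- seq_len(H); ri <- H + zi; ni <- 2L * H + zi
  gW <- matrix(0, N, 3L * H); gU <- matrix(0, H, 3L * H); gb <- rep(0, 3L * H)
  dh_next <- matrix(0, S, H)
  for (s in rev(seq_along(cache))) {
    cc <- cache[[s]]
    t <- cc$t
    dh <- dh_next + matrix(dH_inject[, t, ], S, H)
    dhnew <- dh * cc$m
    dh_prev <- dh * (1 - cc$m)
    dz <- dhnew * (cc$h_prev - cc$n)
    dn <- dhnew * (1 - cc$z)
    dh_prev <- dh_prev + dhnew * cc$z
    x <- matrix(X[, t, ], S, N)

    dn_pre <- dn * (1 - cc$n^2)
    gW[, ni] <- gW[, ni] + crossprod(x, dn_pre)
    gU[, ni] <- gU[, ni] + crossprod(cc$r * cc$h_prev, dn_pre)
    gb[ni] <- gb[ni] + colSums(dn_pre)
    drh <- dn_pre %*% t(gru$U[, ni])
    dr <- drh * cc$h_prev
    dh_prev <- dh_prev + drh * cc$r

    dz_pre <- dz * cc$z * (1 - cc$z)
    gW[, zi] <- gW[, zi] + crossprod(x, dz_pre)
    gU[, zi] <- gU[, zi] + crossprod(cc$h_prev, dz_pre)
    gb[zi] <- gb[zi] + colSums(dz_pre)
    dh_prev <- dh_prev + dz_pre %*% t(gru$U[, zi])

    dr_pre <- dr * cc$r * (1 - cc$r)
    gW[, ri] <- gW[, ri] + crossprod(x, dr_pre)
    gU[, ri] <- gU[, ri] + crossprod(cc$h_prev, dr_pre)
    gb[ri] <- gb[ri] + colSums(dr_pre)
    dh_prev <- dh_prev + dr_pre %*% t(gru$U[, ri])

    dh_next <- dh_prev
  }
  list(W = gW, U = gU, b = gb)
}

#' Forward pass of the conditional RETAIN model
#'
#' Computes time-level attention alpha (masked softmax over week logits from
#' the first GRU), variable-level attention beta (tanh projection of the
#' second GRU), the context vector c = sum_j alpha_j (beta_j * x_j) over
#' unmasked weeks, and the linear prediction y = w . (c + F) + b with no
#' output nonlinearity.
#'
#' @param params A `retain_params` (or a `retain_fit`, whose best parameters
#'   are used).
#' @param X Array (samples x 16 x N) of standardized time-variant inputs.
#' @param F Matrix (samples x K) of standardized time-fixed features.
#' @param mask Prefix mask (samples x 16).
#' @param keep_cache Keep GRU caches (internal, for backprop).
#' @return List with `y_std` (model-scale prediction), `alpha` (samples x
#'   16; masked weeks are exactly 0), `beta` (samples x 16 x N), `context`,
#'   and diagnostic hidden states.
#' @export
retain_forward <- function(params, X, F, mask, keep_cache = FALSE) {
  if (inherits(params, "retain_fit")) params <- params$params
  stopifnot(inherits(params, "retain_params"))
  d <- params$dims
  S <- dim(X)[1]; T <- dim(X)[2]
  stopifnot(dim(X)[3] == d$N, ncol(F) == d$K, ncol(mask) == T)
  if (any(rowSums(mask) == 0)) stop("all-masked sample", call. = FALSE)
  if (anyNA(X) || anyNA(F)) stop("NaN/NA in inputs", call. = FALSE)
  ord <- if (params$reverse_time) rev(seq_len(T)) else seq_len(T)

  ga <- gru_forward(params$gru_a, X, mask, ord, d$H)
  gb <- gru_forward(params$gru_b, X, mask, ord, d$H)

  e <- matrix(0, S, T)
  for (t in seq_len(T))
    e[, t] <- matrix(ga$H[, t, ], S, d$H) %*% params$w_alpha + params$b_alpha
  e[mask == 0] <- -Inf
  mx <- do.call(pmax, as.data.frame(e))
  ex <- exp(e - mx)
  ex[mask == 0] <- 0
  alpha <- ex / rowSums(ex)

  beta <- array(0, c(S, T, d$N))
  context <- matrix(0, S, d$N)
  for (t in seq_len(T)) {
    bt <- tanh(matrix(gb$H[, t, ], S, d$H) %*% params$W_beta +
                 rep(params$b_beta, each = S))
    beta[, t, ] <- bt
    context <- context + alpha[, t] * (bt * matrix(X[, t, ], S, d$N))
  }
  y_std <- as.vector(context %*% params$w_out[seq_len(d$N)] +
                       F %*% params$w_out[d$N + seq_len(d$K)] + params$b_out)
  out <- list(y_std = y_std, alpha = alpha, beta = beta, context = context,
              hidden_g = ga$H, hidden_h = gb$H)
  if (keep_cache) { out$cache_a <- ga$cache; out$cache_b <- gb$cache }
  out
}

retain_backward <- function(params, X, F, mask, fw, dy) {
  d <- params$dims
  S <- dim(X)[1]; T <- dim(X)[2]
  g <- list(gru_a = NULL, gru_b = NULL,
            w_alpha = rep(0, d$H), b_alpha = 0,
            W_beta = matrix(0, d$H, d$N), b_beta = rep(0, d$N),
            w_out = rep(0, d$N + d$K), b_out = 0)
  g$w_out[seq_len(d$N)] <- as.vector(crossprod(fw$context, dy))
  g$w_out[d$N + seq_len(d$K)] <- as.vector(crossprod(F, dy))
  g$b_out <- sum(dy)
  dc <- outer(dy, params$w_out[seq_len(d$N)])

  dalpha <- matrix(0, S, T)
  dHb <- array(0, c(S, T, d$H))
  for (t in seq_len(T)) {
    xt <- matrix(X[, t, ], S, d$N)
    bt <- matrix(fw$beta[, t, ], S, d$N)
    dalpha[, t] <- rowSums(dc * bt * xt)
    dB <- dc * xt * fw$alpha[, t]
    dBpre <- dB * (1 - bt^2)
    ht <- matrix(fw$hidden_h[, t, ], S, d$H)
    g$W_beta <- g$W_beta + crossprod(ht, dBpre)
    g$b_beta <- g$b_beta + colSums(dBpre)
    dHb[, t, ] <- dBpre %*% t(params$W_beta)
  }

  sdot <- rowSums(fw$alpha * dalpha)
  de <- fw$alpha * (dalpha - sdot)
  dGa <- array(0, c(S, T, d$H))
  for (t in seq_len(T)) {
    gt <- matrix(fw$hidden_g[, t, ], S, d$H)
    g$w_alpha <- g$w_alpha + as.vector(crossprod(gt, de[, t]))
    dGa[, t, ] <- outer(de[, t], params$w_alpha)
  }
  g$b_alpha <- sum(de)

  g$gru_a <- gru_backward(params$gru_a, X, fw$cache_a, dGa, d$H)
  g$gru_b <- gru_backward(params$gru_b, X, fw$cache_b, dHb, d$H)
  g
}

# flat-vector view of the trainable parameters (order fixed by this list)
TRAINABLE <- c("gru_a", "gru_b", "w_alpha", "b_alpha", "W_beta", "b_beta",
               "w_out", "b_out")

params_to_vec <- function(p) unlist(p[TRAINABLE], use.names = FALSE)

vec_to_params <- function(vec, template) {
  res <- utils::relist(vec, template[TRAINABLE])
  out <- template
  for (nm in TRAINABLE) out[[nm]] <- res[[nm]]
  out
}

mse_loss <- function(y_hat, y) mean((y_hat - y)^2)

#' Train the conditional RETAIN model
#'
#' Minimizes mean squared error of the (internally standardized) week-16
#' weight over all prefix samples with minibatch Adam. A user-level
#' validation split selects the returned best-on-validation parameters.
#' Deterministic given the config seed under single-threaded execution.
#'
#' @param tensor A standardized `feature_tensor` (see [apply_scaler()]).
#' @param config A [retain_config()].
#' @param verbose Print per-epoch losses.
#' @return A `retain_fit` with `params`, `history` (per-epoch train/val MSE
#'   on the standardized target), `config`, and the attached `scaler`.
#' @export
retain_train <- function(tensor, config = retain_config(), verbose = FALSE) {
  stopifnot(inherits(tensor, "feature_tensor"))
  if (is.null(tensor$scaler))
    stop("tensor must be standardized with apply_scaler()", call. = FALSE)
  S_all <- dim(tensor$X)[1]
  N <- dim(tensor$X)[3]; K <- ncol(tensor$F)
  y_std_all <- (tensor$y - tensor$scaler$y_center) / tensor$scaler$y_scale

  users <- unique(tensor$sample_index$user_id)
  n_val <- floor(config$val_fraction * length(users))
  with_local_seed(config$seed, {
    val_users <- if (n_val > 0) sample(users, n_val) else character(0)
    is_val <- tensor$sample_index$user_id %in% val_users
    tr_idx <- which(!is_val); va_idx <- which(is_val)

    params <- retain_init(N, K, config$hidden_size, seed = config$seed,
                          reverse_time = config$reverse_time)
    vec <- params_to_vec(params)
    # decay mask: recurrent + projection weights only, not the output head
    dm <- params[TRAINABLE]
    for (nm in TRAINABLE)
      dm[[nm]] <- rapply(list(dm[[nm]]),
                         function(x) x * 0 + as.numeric(
                           nm %in% c("gru_a", "gru_b", "w_alpha", "W_beta")),
                         how = "unlist")
    decay_mask <- unlist(dm, use.names = FALSE)
    m <- v <- numeric(length(vec))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    step <- 0L
    best <- list(val = Inf, vec = vec)
    history <- data.frame(epoch = integer(0), train_mse = numeric(0),
                          val_mse = numeric(0))

    eval_mse <- function(vec, idx) {
      if (length(idx) == 0) return(NA_real_)
      p <- vec_to_params(vec, params)
      tot <- 0
      for (chunk in split(idx, ceiling(seq_along(idx) / 4096))) {
        fw <- retain_forward(p, tensor$X[chunk, , , drop = FALSE],
                             tensor$F[chunk, , drop = FALSE],
                             tensor$mask[chunk, , drop = FALSE])
        tot <- tot + sum((fw$y_std - y_std_all[chunk])^2)
      }
      tot / length(idx)
    }

    # The output head is linear given the attentions, so its exact MSE
    # minimizer has a closed form: ridge-stabilized least squares of the
    # target on [context, F, 1] over the training samples.
    head_idx <- length(vec) - (N + K) : 0   # w_out then b_out (last N+K+1)
    refit_head <- function(vec) {
      p <- vec_to_params(vec, params)
      M <- matrix(0, length(tr_idx), N + K + 1)
      for (chunk in split(seq_along(tr_idx), ceiling(seq_along(tr_idx) / 4096))) {
        ix <- tr_idx[chunk]
        fw <- retain_forward(p, tensor$X[ix, , , drop = FALSE],
                             tensor$F[ix, , drop = FALSE],
                             tensor$mask[ix, , drop = FALSE])
        M[chunk, ] <- cbind(fw$context, tensor$F[ix, , drop = FALSE], 1)
      }
      A <- crossprod(M) + 1e-8 * diag(N + K + 1)
      w <- solve(A, crossprod(M, y_std_all[tr_idx]))
      vec[head_idx] <- as.vector(w)
      vec
    }

    for (ep in seq_len(config$epochs)) {
      perm <- sample(tr_idx)
      batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
      ep_loss <- 0
      for (bt in batches) {
        p <- vec_to_params(vec, params)
        Xb <- tensor$X[bt, , , drop = FALSE]
        Fb <- tensor$F[bt, , drop = FALSE]
        Mb <- tensor$mask[bt, , drop = FALSE]
        fw <- retain_forward(p, Xb, Fb, Mb, keep_cache = TRUE)
        res <- fw$y_std - y_std_all[bt]
        ep_loss <- ep_loss + sum(res^2)
        if (!all(is.finite(res)))
          stop("training diverged: non-finite loss at epoch ", ep,
               call. = FALSE)
        grads <- retain_backward(p, Xb, Fb, Mb, fw, 2 * res / length(bt))
        gvec <- params_to_vec(grads)
        step <- step + 1L
        m <- b1 * m + (1 - b1) * gvec
        v <- b2 * v + (1 - b2) * gvec^2
        mhat <- m / (1 - b1^step)
        vhat <- v / (1 - b2^step)
        vec <- vec - config$learning_rate *
          (mhat / (sqrt(vhat) + eps) +
             (config$weight_decay %||% 0) * decay_mask * vec)
      }
      vec <- refit_head(vec)
      tr_mse <- ep_loss / length(tr_idx)
      va_mse <- eval_mse(vec, va_idx)
      history <- rbind(history, data.frame(epoch = ep, train_mse = tr_mse,
                                           val_mse = va_mse))
      track <- if (is.na(va_mse)) tr_mse else va_mse
      if (track < best$val) best <- list(val = track, vec = vec)
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  val %.5f", ep, tr_mse,
                        if (is.na(va_mse)) NaN else va_mse))
    }
    structure(list(params = vec_to_params(best$vec, params),
                   final_params = vec_to_params(vec, params),
                   history = history, config = config,
                   scaler = tensor$scaler, vars = tensor$vars,
                   fixed_vars = colnames(tensor$F)),
              class = "retain_fit")
  })
}

#' @export
print.retain_fit <- function(x, ...) {
  h <- x$history
  cat("Conditional RETAIN fit:", x$params$dims$N, "time-variant +",
      x$params$dims$K, "fixed variables | hidden", x$params$dims$H, "\n")
  cat(sprintf("epochs: %d | final train MSE %.5f | best val MSE %.5f\n",
              nrow(h), h$train_mse[nrow(h)], min(h$val_mse, na.rm = TRUE)))
  invisible(x)
}

#' Predict week-16 weight for every prefix sample
#'
#' @param fit A `retain_fit`.
#' @param tensor A standardized `feature_tensor` (same scaler as training).
#' @param type `"kg"` (back-transformed, default) or `"std"` (model scale).
#' @param batch_size Samples per forward batch.
#' @return Numeric vector of predictions, one per sample, in `tensor`
#'   sample order.
#' @export
retain_predict <- function(fit, tensor, type = c("kg", "std"),
                           batch_size = 4096L) {
  stopifnot(inherits(fit, "retain_fit"), inherits(tensor, "feature_tensor"))
  type <- match.arg(type)
  if (is.null(tensor$scaler))
    stop("tensor must be standardized with the training scaler",
         call. = FALSE)
  if (!identical(tensor$vars, fit$vars))
    stop("tensor variables do not match the fitted model", call. = FALSE)
  S <- dim(tensor$X)[1]
  out <- numeric(S)
  for (chunk in split(seq_len(S), ceiling(seq_len(S) / batch_size))) {
    fw <- retain_forward(fit$params, tensor$X[chunk, , , drop = FALSE],
                         tensor$F[chunk, , drop = FALSE],
                         tensor$mask[chunk, , drop = FALSE])
    out[chunk] <- fw$y_std
  }
  if (type == "kg") out * fit$scaler$y_scale + fit$scaler$y_center else out
}
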