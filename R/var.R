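# Multitrial VAR estimation. Each trial contributes its own lagged
# regression rows; cross-products are accumulated per trial so that trial
# bootstrap and label shuffling reduce to reweighting cached Gram blocks.

# per-trial cross products for window data x: trials x k x w
# returns matrix (kp*kp + kp*k + k*k) x n_trials of stacked vec(Sxx, Sxy, Syy);
# `start` fixes the first predicted sample (>= p + 1) so that different
# orders can be compared on a common observation range
var_gram_trials <- function(x, p, start = p + 1) {
  n <- dim(x)[1]; k <- dim(x)[2]; w <- dim(x)[3]
  if (w <= p || start > w) abort_data("window shorter than VAR order + 1")
  d <- k * p
  out <- matrix(0, d * d + d * k + k * k, n)
  idx_t <- start:w
  for (tr in seq_len(n)) {
    xt <- matrix(x[tr, , ], k, w)
    Y <- t(xt[, idx_t, drop = FALSE])                  # (w-p) x k
    X <- matrix(0, length(idx_t), d)
    for (m in seq_len(p)) {
      X[, ((m - 1) * k + 1):(m * k)] <- t(xt[, idx_t - m, drop = FALSE])
    }
    out[, tr] <- c(crossprod(X), crossprod(X, Y), crossprod(Y))
  }
  out
}

# solve the VAR from accumulated cross products
var_from_gram <- function(g, k, p, n_obs) {
  d <- k * p
  Sxx <- matrix(g[seq_len(d * d)], d, d)
  Sxy <- matrix(g[d * d + seq_len(d * k)], d, k)
  Syy <- matrix(g[d * d + d * k + seq_len(k * k)], k, k)
  Bhat <- tryCatch(solve(Sxx, Sxy), error = function(e) {
    abort_data("singular regressor covariance in VAR fit")
  })
  sigma <- (Syy - crossprod(Sxy, Bhat)) / n_obs
  sigma <- (sigma + t(sigma)) / 2
  A <- lapply(seq_len(p), function(m) {
    t(Bhat[((m - 1) * k + 1):(m * k), , drop = FALSE])
  })
  new_var_model(A, sigma, n_obs)
}

new_var_model <- function(A, sigma, n_obs = NA_real_, window = NA_integer_) {
  k <- nrow(A[[1]])
  structure(
    list(A = A, sigma = sigma, p = length(A), k = k,
         n_obs = n_obs, window = window),
    class = "ercnet_var"
  )
}

#' @export
print.ercnet_var <- function(x, ...) {
  cat(sprintf("<ercnet_var> k = %d, p = %d, %s observations (spectral radius %.3f)\n",
              x$k, x$p, format(x$n_obs), companion_radius(x$A)))
  invisible(x)
}

# spectral radius of the companion matrix of coefficient list A
companion_radius <- function(A) {
  p <- length(A); k <- nrow(A[[1]])
  comp <- matrix(0, k * p, k * p)
  comp[seq_len(k), ] <- do.call(cbind, A)
  if (p > 1) {
    comp[(k + 1):(k * p), seq_len(k * (p - 1))] <- diag(k * (p - 1))
  }
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Fit a VAR to one window of multitrial data
#'
#' Least squares over trial-stacked lagged regressions: every trial
#' contributes its own lag pairs so no lags bleed across trial
#' boundaries. The innovation covariance is the maximum-likelihood
#' residual covariance.
#'
#' @param x Numeric array, trials x channels x samples (one window).
#' @param p Model order (samples of history).
#' @return An `ercnet_var` with coefficient matrices `A` (list of k x k,
#'   `A[[m]][i, j]` = effect of channel j at lag m on channel i),
#'   innovation covariance `sigma`, and metadata.
#' @export
fit_var_multitrial <- function(x, p) {
  if (length(dim(x)) != 3) abort_config("`x` must be trials x channels x samples")
  n <- dim(x)[1]; w <- dim(x)[3]
  g <- rowSums(var_gram_trials(x, p))
  var_from_gram(g, dim(x)[2], p, n * (w - p))
}

#' Select the VAR order by AIC
#'
#' `AIC(p) = log det(Sigma_p) + 2 k^2 p / N_eff` with `N_eff` the number
#' of usable regression rows (vector observations) pooled over trials.
#' All candidate orders are evaluated on the common observation range
#' `(p_max + 1):w` so their likelihoods are comparable. Ties go to the
#' smaller order.
#'
#' @param x Numeric array, trials x channels x samples.
#' @param p_max Largest order considered; must pass the sample budget.
#' @param p_min Smallest order considered.
#' @return A list: `p` (selected), `aic` (tibble of order, aic).
#' @export
select_order_aic <- function(x, p_max, p_min = 1) {
  n <- dim(x)[1]; k <- dim(x)[2]; w <- dim(x)[3]
  if (p_max < p_min || p_min < 1) abort_config("need 1 <= p_min <= p_max")
  budget <- check_sample_budget(w, k, p_max, n)
  if (!budget$pass) {
    abort_config(sprintf(
      "p_max = %d exceeds the sample budget (need window >= %.1f samples)",
      p_max, budget$w_min))
  }
  aic <- vapply(p_min:p_max, function(p) {
    g <- rowSums(var_gram_trials(x, p, start = p_max + 1))
    n_obs <- n * (w - p_max)
    m <- var_from_gram(g, k, p, n_obs)
    det_s <- determinant(m$sigma, logarithm = TRUE)
    as.numeric(det_s$modulus) + 2 * k^2 * p / n_obs
  }, 0)
  orders <- p_min:p_max
  list(
    p = orders[which.min(aic)],
    aic = tibble::tibble(order = orders, aic = aic)
  )
}
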