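# VAR model validation: residual whiteness (multivariate portmanteau),
# consistency against data simulated from the fitted model, and KPSS
# level-stationarity per channel.

#' KPSS level-stationarity test
#'
#' Statistic for the null of level stationarity, with Bartlett-window
#' long-run variance. Critical values (0.347, 0.463, 0.574, 0.739 at
#' 10/5/2.5/1 percent) are the standard asymptotic ones.
#'
#' @param y Numeric vector.
#' @param lags Bartlett truncation lag; default `4 * (n/100)^(1/4)`.
#' @param alpha Significance level (one of 0.10, 0.05, 0.025, 0.01).
#' @return List with `statistic`, `lags`, `critical`, `pass`
#'   (TRUE = stationarity not rejected).
#' @export
kpss_level <- function(y, lags = NULL, alpha = 0.05) {
  n <- length(y)
  if (n < 8) abort_data("KPSS needs at least 8 observations")
  lags <- lags %||% max(1L, trunc(4 * (n / 100)^0.25))
  crit <- c(`0.1` = 0.347, `0.05` = 0.463, `0.025` = 0.574, `0.01` = 0.739)
  key <- as.character(alpha)
  if (!key %in% names(crit)) abort_config("alpha must be 0.10, 0.05, 0.025 or 0.01")
  e <- y - mean(y)
  s2 <- sum(e^2) / n
  if (lags > 0) {
    for (l in seq_len(lags)) {
      s2 <- s2 + 2 * (1 - l / (lags + 1)) * sum(e[(l + 1):n] * e[1:(n - l)]) / n
    }
  }
  s2 <- max(s2, .Machine$double.eps)
  stat <- sum(cumsum(e)^2) / (n^2 * s2)
  list(statistic = stat, lags = lags, critical = unname(crit[key]),
       pass = stat < crit[key])
}

# per-trial residuals of a fitted VAR on window data trials x k x w
var_residuals <- function(model, x) {
  n <- dim(x)[1]; k <- dim(x)[2]; w <- dim(x)[3]
  p <- model$p
  idx <- (p + 1):w
  res <- array(0, c(n, k, length(idx)))
  for (tr in seq_len(n)) {
    xt <- matrix(x[tr, , ], k, w)
    pred <- matrix(0, k, length(idx))
    for (m in seq_len(p)) pred <- pred + model$A[[m]] %*% xt[, idx - m, drop = FALSE]
    res[tr, , ] <- xt[, idx, drop = FALSE] - pred
  }
  res
}

# multivariate Ljung-Box portmanteau on residual autocorrelations,
# accumulated within trials only
portmanteau <- function(res, p, h = 10) {
  n <- dim(res)[1]; k <- dim(res)[2]; tt <- dim(res)[3]
  h <- min(h, tt - 1)
  if (h <= p) h <- p + 1
  if (h >= tt) abort_data("too few residuals for the whiteness test")
  N <- n * tt
  C0 <- matrix(0, k, k)
  for (tr in seq_len(n)) {
    e <- matrix(res[tr, , ], k, tt)
    C0 <- C0 + tcrossprod(e)
  }
  C0 <- C0 / N
  C0i <- solve(C0 + diag(1e-12, k))
  Q <- 0
  for (l in seq_len(h)) {
    Cl <- matrix(0, k, k)
    for (tr in seq_len(n)) {
      e <- matrix(res[tr, , ], k, tt)
      Cl <- Cl + e[, (l + 1):tt, drop = FALSE] %*% t(e[, 1:(tt - l), drop = FALSE])
    }
    Cl <- Cl / N
    Q <- Q + sum(diag(t(Cl) %*% C0i %*% Cl %*% C0i)) / (N - l)
  }
  Q <- N^2 * Q
  df <- k^2 * (h - p)
  list(Q = Q, df = df, p_value = stats::pchisq(Q, df, lower.tail = FALSE))
}

# simulate trials from a fitted VAR (used by the consistency check)
simulate_var_trials <- function(model, n_trials, n_samples, burnin = 100) {
  k <- model$k; p <- model$p
  L <- t(chol(model$sigma + diag(1e-12, k)))
  out <- array(0, c(n_trials, k, n_samples))
  total <- n_samples + burnin
  for (tr in seq_len(n_trials)) {
    x <- matrix(0, k, total)
    innov <- L %*% matrix(rnorm(k * total), k)
    for (t in (p + 1):total) {
      acc <- innov[, t]
      for (m in seq_len(p)) acc <- acc + model$A[[m]] %*% x[, t - m]
      x[, t] <- acc
    }
    out[tr, , ] <- x[, (burnin + 1):total]
  }
  out
}

# lag-0 and lag-1 cross-correlation summary used by the consistency test
crosscorr_01 <- function(x) {
  n <- dim(x)[1]; k <- dim(x)[2]; tt <- dim(x)[3]
  R0 <- matrix(0, k, k); R1 <- matrix(0, k, k)
  for (tr in seq_len(n)) {
    e <- matrix(x[tr, , ], k, tt)
    e <- e - rowMeans(e)
    R0 <- R0 + tcrossprod(e) / tt
    R1 <- R1 + e[, 2:tt, drop = FALSE] %*% t(e[, 1:(tt - 1), drop = FALSE]) / (tt - 1)
  }
  d <- sqrt(pmax(diag(R0), .Machine$double.eps))
  sc <- tcrossprod(d)
  c(R0 / sc, R1 / sc) / n
}

#' Validate a fitted VAR
#'
#' Three checks: (1) whiteness — multivariate portmanteau test on the
#' residual autocorrelations; (2) consistency — the fitted model is
#' simulated with matched trial count and length, and the lag-0/1
#' cross-correlation pattern is compared with the data's
#' (`100 * (1 - |R_sim - R_dat| / |R_dat|)`, pass at >= 80); (3)
#' level stationarity — KPSS per channel on the trial-averaged series.
#'
#' @param model An `ercnet_var`.
#' @param x The window data the model was fitted on (trials x k x w).
#' @param h Portmanteau lag span.
#' @param alpha Significance level for whiteness and KPSS.
#' @return A list: `whiteness` (Q, df, p_value, pass), `consistency`
#'   (percent, pass), `kpss` (tibble per channel), `stationary`
#'   (fraction of channels passing KPSS).
#' @export
validate_var <- function(model, x, h = 10, alpha = 0.05) {
  res <- var_residuals(model, x)
  wh <- portmanteau(res, model$p, h = h)
  wh$pass <- wh$p_value > alpha

  sim <- simulate_var_trials(model, dim(x)[1], dim(x)[3])
  r_dat <- crosscorr_01(x)
  r_sim <- crosscorr_01(sim)
  cons <- 100 * (1 - sqrt(sum((r_sim - r_dat)^2)) /
                   max(sqrt(sum(r_dat^2)), .Machine$double.eps))

  k <- dim(x)[2]
  kp <- lapply(seq_len(k), function(ch) {
    kpss_level(colMeans(matrix(x[, ch, ], dim(x)[1])), alpha = alpha)
  })
  kpss_tbl <- tibble::tibble(
    channel = seq_len(k),
    statistic = vapply(kp, `[[`, 0, "statistic"),
    critical = vapply(kp, `[[`, 0, "critical"),
    pass = vapply(kp, `[[`, TRUE, "pass")
  )
  list(
    whiteness = wh,
    consistency = list(percent = cons, pass = cons >= 80),
    kpss = kpss_tbl,
    stationary = mean(kpss_tbl$pass)
  )
}
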