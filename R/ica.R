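# Independent component analysis: variance-based model order, fixed-point
# negentropy maximization with restart aggregation, and artifact-component
# screening.

#' Choose the ICA model order by explained variance
#'
#' The smallest number of leading covariance eigenvalues whose
#' cumulative sum reaches `fraction` of the total variance.
#'
#' @param eigenvalues Nonnegative eigenvalues, sorted descending.
#' @param fraction Target variance fraction.
#' @return Integer order.
#' @export
#' @examples
#' choose_order_by_variance(c(0.5, 0.3, 0.15, 0.05)) # 3
choose_order_by_variance <- function(eigenvalues, fraction = 0.90) {
  if (!length(eigenvalues)) abort_config("no eigenvalues supplied")
  if (any(eigenvalues < -1e-12)) abort_config("eigenvalues must be nonnegative")
  if (is.unsorted(rev(eigenvalues))) abort_config("eigenvalues must be sorted descending")
  cum <- cumsum(eigenvalues) / sum(eigenvalues)
  as.integer(which(cum >= fraction - 1e-12)[1])
}

#' Decompose a recording into independent source components
#'
#' PCA whitening to `m` dimensions followed by symmetric fixed-point
#' ICA (tanh contrast). The decomposition is run `restarts` times from
#' different random rotations; the pooled components are clustered on
#' the absolute correlation of their source series (average linkage,
#' `m` clusters) and each cluster's centrotype is returned, with a
#' stability index (mean within-cluster similarity) per component.
#' Components are signed so that each one's largest-magnitude channel
#' weight is positive. ICA is fitted on all trials pooled across the
#' two perception conditions so both share one basis.
#'
#' @param rec An `ercnet_recording` (or channels x samples matrix).
#' @param m Model order; default chosen by [choose_order_by_variance()].
#' @param variance_fraction Used when `m` is `NULL`.
#' @param restarts Number of random restarts (>= 2 for stability
#'   indexing).
#' @param seed Integer seed.
#' @param max_iter,tol Fixed-point iteration controls.
#' @param max_samples Cap on the number of time samples used to fit the
#'   rotation (the full series is still projected); keeps large
#'   recordings tractable.
#' @return An `ercnet_ica`: `unmixing` (m x channels), `mixing`
#'   (channels x m, pseudo-inverse), `sources` (trials x m x samples),
#'   `variance_explained`, `stability` (per component), `kept`
#'   (initially all), `order` m.
#' @export
decompose <- function(rec, m = NULL, variance_fraction = 0.90,
                      restarts = 20, seed = 1, max_iter = 200,
                      tol = 1e-6, max_samples = 1e5) {
  if (inherits(rec, "ercnet_recording")) {
    d <- dim(rec$data)
    X <- matrix(aperm(rec$data, c(2, 3, 1)), d[2])
    n_trials <- d[1]; n_samp <- d[3]
  } else {
    X <- rec
    n_trials <- 1; n_samp <- ncol(X)
  }
  if (restarts < 2) abort_config("need >= 2 restarts for stability indexing")
  set.seed(seed)
  mu <- rowMeans(X)
  X <- X - mu
  n_ch <- nrow(X)
  cv <- tcrossprod(X) / ncol(X)
  eg <- eigen(cv, symmetric = TRUE)
  evals <- pmax(eg$values, 0)
  m <- m %||% choose_order_by_variance(evals, variance_fraction)
  if (m > n_ch) abort_config("model order exceeds channel count")
  V <- diag(1 / sqrt(evals[seq_len(m)]), m) %*% t(eg$vectors[, seq_len(m), drop = FALSE])
  fit_cols <- if (ncol(X) > max_samples) {
    sort(sample.int(ncol(X), max_samples))
  } else {
    seq_len(ncol(X))
  }
  Z <- V %*% X[, fit_cols, drop = FALSE]

  runs <- list()
  for (rs in seq_len(restarts)) {
    W <- fixed_point_ica(Z, max_iter = max_iter, tol = tol)
    if (!is.null(W)) runs[[length(runs) + 1]] <- W
  }
  if (!length(runs)) abort_data("ICA failed to converge in every restart")

  # aggregate restarts: cluster pooled components on |corr| of sources
  W_all <- do.call(rbind, runs)
  S_all <- W_all %*% Z
  cors <- abs(stats::cor(t(S_all)))
  hc <- stats::hclust(stats::as.dist(1 - cors), method = "average")
  cl <- stats::cutree(hc, k = m)
  W_sel <- matrix(0, m, m)
  stability <- numeric(m)
  for (ci in seq_len(m)) {
    members <- which(cl == ci)
    sim <- cors[members, members, drop = FALSE]
    cent <- members[which.max(rowSums(sim))]
    W_sel[ci, ] <- W_all[cent, ]
    stability[ci] <- mean(sim)
  }

  unmixing <- W_sel %*% V
  mixing <- pinv(unmixing)
  # sign convention: largest-|weight| channel weight positive
  for (ci in seq_len(m)) {
    s <- sign(mixing[which.max(abs(mixing[, ci])), ci])
    if (s < 0) {
      mixing[, ci] <- -mixing[, ci]
      unmixing[ci, ] <- -unmixing[ci, ]
    }
  }
  S_full <- unmixing %*% X
  sources <- aperm(array(S_full, c(m, n_samp, n_trials)), c(3, 1, 2))

  structure(
    list(
      unmixing = unmixing, mixing = mixing, sources = sources,
      center = mu, order = m,
      variance_explained = sum(evals[seq_len(m)]) / sum(evals),
      stability = stability,
      kept = seq_len(m),
      eigenvalues = evals,
      seed = seed
    ),
    class = "ercnet_ica"
  )
}

#' @export
print.ercnet_ica <- function(x, ...) {
  cat(sprintf(
    "<ercnet_ica> %d components (%.1f%% variance), %d kept; stability %.2f-%.2f\n",
    x$order, 100 * x$variance_explained, length(x$kept),
    min(x$stability), max(x$stability)
  ))
  invisible(x)
}

# symmetric fixed-point iteration with tanh contrast on whitened data;
# returns the m x m rotation or NULL on non-convergence
fixed_point_ica <- function(Z, max_iter = 200, tol = 1e-6) {
  m <- nrow(Z)
  n <- ncol(Z)
  W <- sym_orth(matrix(rnorm(m * m), m))
  for (it in seq_len(max_iter)) {
    Y <- W %*% Z
    G <- tanh(Y)
    W_new <- (G %*% t(Z)) / n - diag(rowMeans(1 - G^2)) %*% W
    W_new <- sym_orth(W_new)
    delta <- 1 - min(abs(diag(W_new %*% t(W))))
    W <- W_new
    if (delta < tol) return(W)
  }
  NULL
}

sym_orth <- function(W) {
  s <- svd(W)
  s$u %*% t(s$v)
}

pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Screen out artifactual independent components
#'
#' A component is discarded when (a) the kurtosis of its source series
#' is an outlier across components (robust z above `kurtosis_z`) —
#' extreme-value artifacts; or (b) its band-averaged log spectral power
#' is an outlier across components in any screening band (robust z
#' above `spectral_z`) — abnormal spectra.
#'
#' With fewer than `min_components` components the cross-component
#' robust z is too unstable to be meaningful, so nothing is removed
#' (the report is still computed).
#'
#' @param model An `ercnet_ica`.
#' @param fs Sampling rate of the source series (Hz).
#' @param kurtosis_z,spectral_z Robust-z thresholds (`Inf` disables).
#' @param bands Screening bands in Hz.
#' @param min_components Minimum component count for removals to apply.
#' @return The model with `kept` updated and a `screening` report
#'   tibble attached (component, kurtosis_z, max_spectral_z, removed,
#'   reason).
#' @export
screen_components <- function(model, fs, kurtosis_z = 4, spectral_z = 4,
                              bands = default_artifact_bands(),
                              min_components = 8) {
  d <- dim(model$sources)
  m <- d[2]
  flat <- matrix(aperm(model$sources, c(2, 3, 1)), m)
  kurt <- apply(flat, 1, function(y) {
    y <- y - mean(y)
    mean(y^4) / (mean(y^2)^2) - 3
  })
  kz <- robust_z(kurt)

  bands <- lapply(bands, function(b) c(b[1], min(b[2], fs / 2)))
  bands <- bands[vapply(bands, function(b) b[2] > b[1], TRUE)]
  n_samp <- d[3]
  fgrid <- seq_len(floor(n_samp / 2)) * fs / n_samp
  # average per-trial spectra to limit memory
  bp <- matrix(0, m, length(bands))
  for (tr in seq_len(d[1])) {
    pw <- Mod(stats::mvfft(t(matrix(model$sources[tr, , ], m))))^2 / n_samp
    for (bi in seq_along(bands)) {
      sel <- which(fgrid >= bands[[bi]][1] & fgrid < bands[[bi]][2])
      if (length(sel)) bp[, bi] <- bp[, bi] + colMeans(pw[sel + 1, , drop = FALSE])
    }
  }
  bp <- log(bp / d[1] + .Machine$double.eps)
  sz <- apply(bp, 2, robust_z)
  sz_max <- apply(abs(sz), 1, max)

  removed_kurt <- abs(kz) > kurtosis_z
  removed_spec <- sz_max > spectral_z
  if (m < min_components) {
    removed_kurt[] <- FALSE
    removed_spec[] <- FALSE
  }
  removed <- removed_kurt | removed_spec
  if (all(removed)) abort_data("all components would be removed")
  model$kept <- which(!removed)
  model$screening <- tibble::tibble(
    component = seq_len(m),
    kurtosis_z = kz,
    max_spectral_z = sz_max,
    removed = removed,
    reason = dplyr::case_when(
      removed_kurt & removed_spec ~ "extreme values + abnormal spectrum",
      removed_kurt ~ "extreme values",
      removed_spec ~ "abnormal spectrum",
      TRUE ~ ""
    )
  )
  model
}

#' Source series of the kept components
#'
#' @param model An `ercnet_ica` (after [screen_components()] if
#'   screening is wanted).
#' @return Array trials x kept-components x samples.
#' @export
kept_sources <- function(model) {
  model$sources[, model$kept, , drop = FALSE]
}
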