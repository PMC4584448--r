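# Spectral transfer function and the DTF family of causality measures.

#' Spectral transfer function of a VAR model
#'
#' `A(f) = I - sum_m A_m exp(-i 2 pi f m / fs)`; `H(f) = A(f)^{-1}`.
#'
#' @param model An `ercnet_var` (or list with `A`, `k`, `p`).
#' @param freqs Frequency grid in Hz, inside (0, fs/2).
#' @param fs Sampling rate in Hz.
#' @return Complex array k x k x length(freqs).
#' @export
spectral_transfer <- function(model, freqs, fs) {
  if (any(freqs <= 0) || any(freqs >= fs / 2)) {
    abort_config("frequencies must lie strictly inside (0, fs/2)")
  }
  k <- model$k
  H <- array(complex(real = 0), c(k, k, length(freqs)))
  I_k <- diag(k) + 0i
  E <- exp(outer(seq_len(model$p), freqs, function(m, f) -2i * pi * f * m / fs))
  fi <- 0L
  tryCatch(
    for (fi in seq_along(freqs)) {
      Af <- I_k
      for (m in seq_len(model$p)) Af <- Af - model$A[[m]] * E[m, fi]
      H[, , fi] <- solve.default(Af)
    },
    error = function(e) abort_data(sprintf("singular A(f) at %.3g Hz", freqs[fi]))
  )
  H
}

#' DTF, full-frequency DTF, partial coherence and direct DTF
#'
#' From the transfer function `H(f)` and innovation covariance `Sigma`:
#' `DTF^2_{i<-j}(f) = |H_ij|^2 / sum_m |H_im(f)|^2`;
#' `ffDTF^2_{i<-j}(f) = |H_ij(f)|^2 / sum_f sum_m |H_im(f)|^2`;
#' partial coherence `chi^2_ij(f) = |P_ij|^2 / (P_ii P_jj)` with
#' `P = S(f)^{-1}`, `S = H Sigma H*`; and the direct DTF
#' `dDTF = ffDTF * chi`, which suppresses influences mediated by third
#' channels.
#'
#' @param model An `ercnet_var`.
#' @param freqs Frequency grid in Hz.
#' @param fs Sampling rate in Hz.
#' @return A list of k x k x F arrays `dtf`, `ffdtf`, `pcoh`, `ddtf`
#'   (sinks in rows, sources in columns; diagonals are reported but
#'   carry no between-channel meaning).
#' @export
ddtf <- function(model, freqs, fs) {
  H <- spectral_transfer(model, freqs, fs)
  ddtf_from_transfer(H, model$sigma)
}

ddtf_from_transfer <- function(H, sigma) {
  k <- dim(H)[1]
  nf <- dim(H)[3]
  H2 <- Mod(H)^2
  row_tot_f <- apply(H2, c(1, 3), sum)         # k x F: sum over sources
  row_tot <- rowSums(row_tot_f)                # k: sum over sources and freqs
  dtf2 <- sweep(H2, c(1, 3), pmax(row_tot_f, .Machine$double.eps), "/")
  ff2 <- sweep(H2, 1, pmax(row_tot, .Machine$double.eps), "/")
  pc2 <- array(0, dim(H))
  di <- seq(1, k * k, by = k + 1)
  fi <- 0L
  tryCatch(
    for (fi in seq_len(nf)) {
      Hf <- H[, , fi]
      S <- Hf %*% sigma %*% Conj(t(Hf))
      P <- solve.default(S)
      pm2 <- Mod(P)^2
      dd <- pmax(pm2[di], .Machine$double.eps)
      pc2[, , fi] <- pm2 / sqrt(outer(dd, dd))
    },
    error = function(e) {
      abort_data(sprintf("singular spectral matrix at frequency index %d", fi))
    }
  )
  pc2[pc2 > 1] <- 1
  out <- list(
    dtf = sqrt(dtf2),
    ffdtf = sqrt(ff2),
    pcoh = sqrt(Re(pc2)),
    ddtf = sqrt(ff2) * sqrt(Re(pc2))
  )
  if (!all(vapply(out, function(a) all(is.finite(a)), TRUE))) {
    abort_data("non-finite causality values")
  }
  out
}

#' Per-trial-type sliding-window causality maps
#'
#' Fits one VAR per (trial type, window) over that type's trial
#' ensemble and evaluates the DTF family on the frequency grid.
#'
#' @param sources Numeric array trials x k x samples (source signals).
#' @param types Character/factor vector of trial-type labels (length =
#'   trials).
#' @param grid An [segment()] window grid.
#' @param p VAR order.
#' @param freqs Frequency grid in Hz.
#' @param fs Sampling rate in Hz.
#' @param measure Which measure to store, default `"ddtf"`; `"all"`
#'   stores the four arrays.
#' @return A named list (one entry per trial type) of `ercnet_causality_map`
#'   objects: arrays k x k x n_windows x F with attributes `measure`,
#'   `freqs`, `centers_s`.
#' @export
causality_maps <- function(sources, types, grid, p, freqs, fs,
                           measure = c("ddtf", "all")) {
  measure <- match.arg(measure)
  ws <- causality_workspace(sources, types, grid, p, freqs, fs)
  out <- lapply(levels(ws$types), function(ty) {
    counts <- as.numeric(ws$types == ty)
    map_from_counts(ws, counts, measure = measure)
  })
  names(out) <- levels(ws$types)
  out
}

#' Build a causality workspace for a set of source signals
#'
#' Precomputes the sliding-window grid and the per-trial regression
#' cross-products so that dDTF for any trial subset — observed trial
#' types, bootstrap resamples, shuffled labels — is a cheap
#' reweighting. The VAR order is selected by AIC (median selection over
#' up to `aic_windows` evenly spaced windows using all trials) unless
#' given; the sample budget is checked against the smallest trial-type
#' count.
#'
#' @param sources Numeric array trials x k x samples.
#' @param types Trial-type label per trial.
#' @param fs Sampling rate (Hz).
#' @param window_ms,step_ms Sliding-window parameters.
#' @param freqs Frequency grid (Hz), default [freq_grid()].
#' @param p VAR order; `NULL` selects by AIC up to `p_max`.
#' @param p_max Largest order considered by AIC.
#' @param aic_windows Number of windows polled for order selection.
#' @return A workspace list (`grid`, `freqs`, `p`, `types`, Gram cache)
#'   consumed by [delta_erc()], [erc_contrasts()] and
#'   [loading_significance()].
#' @export
build_workspace <- function(sources, types, fs, window_ms = 250,
                            step_ms = 50, freqs = freq_grid(), p = NULL,
                            p_max = 8, aic_windows = 5) {
  grid <- segment(dim(sources)[3], fs, window_ms, step_ms)
  k <- dim(sources)[2]
  if (is.null(p)) {
    polled <- unique(round(seq(1, grid$n_windows,
                               length.out = min(aic_windows, grid$n_windows))))
    picks <- vapply(polled, function(wi) {
      sl <- grid$starts[wi]:(grid$starts[wi] + grid$w - 1)
      select_order_aic(sources[, , sl, drop = FALSE], p_max)$p
    }, 0)
    p <- as.integer(round(median(picks)))
  }
  n_min <- min(table(types))
  budget <- check_sample_budget(grid$w, k, p, n_min)
  if (!budget$pass) {
    warn(sprintf(
      "sample budget violated: window %d < required %.1f samples",
      grid$w, budget$w_min))
  }
  ws <- causality_workspace(sources, types, grid, p, freqs, fs)
  ws$budget <- budget
  ws
}

#' Baseline window indices of a grid
#'
#' Windows lying entirely inside the timeline's baseline interval
#' (within the Waiting period).
#'
#' @param grid An [segment()] grid.
#' @param timeline A [task_timeline()].
#' @return Integer window indices.
#' @export
baseline_windows <- function(grid, timeline) {
  bw <- windows_in_interval(grid, timeline$baseline[1], timeline$baseline[2])
  if (!length(bw)) abort_data("no window fits inside the baseline interval")
  bw
}

# Gram-cache workspace: everything needed to recompute dDTF for any
# weighting of trials (bootstrap resamples, shuffled labels) cheaply.
causality_workspace <- function(sources, types, grid, p, freqs, fs) {
  stopifnot(length(dim(sources)) == 3)
  n <- dim(sources)[1]; k <- dim(sources)[2]
  if (length(types) != n) abort_data("labels length must equal trial count")
  types <- factor(types)
  d <- k * p
  nfeat <- d * d + d * k + k * k
  gram <- matrix(0, nfeat * grid$n_windows, n)
  for (wi in seq_len(grid$n_windows)) {
    sl <- grid$starts[wi]:(grid$starts[wi] + grid$w - 1)
    gram[((wi - 1) * nfeat + 1):(wi * nfeat), ] <-
      var_gram_trials(sources[, , sl, drop = FALSE], p)
  }
  list(
    gram = gram, nfeat = nfeat, n_trials = n, k = k, p = p,
    grid = grid, freqs = freqs, fs = fs, types = types
  )
}

# dDTF (or all measures) for a weighted trial multiset; the compiled
# route is the default, the pure-R route ("r") is the cross-checked
# reference
map_from_counts <- function(ws, counts, measure = "ddtf",
                            engine = ws$engine %||% "cpp") {
  n_used <- sum(counts)
  if (n_used < 2) abort_data("need at least 2 trials per type")
  nz <- which(counts != 0)
  g_all <- matrix(ws$gram[, nz, drop = FALSE] %*% counts[nz],
                  ws$nfeat, ws$grid$n_windows)
  nf <- length(ws$freqs)
  k <- ws$k
  n_w <- ws$grid$n_windows
  if (engine == "cpp") {
    res <- .ddtf_from_gram_cpp(g_all, k, ws$p,
                               n_used * (ws$grid$w - ws$p),
                               ws$freqs, ws$fs, measure == "all")
    arr <- array(res$ddtf, c(k, k, n_w, nf))
    extra <- if (measure == "all") {
      lapply(res[c("dtf", "ffdtf", "pcoh")], array, dim = c(k, k, n_w, nf))
    }
  } else {
    arr <- array(0, c(k, k, n_w, nf))
    extra <- if (measure == "all") {
      list(dtf = arr, ffdtf = arr, pcoh = arr)
    }
    for (wi in seq_len(n_w)) {
      m <- var_from_gram(g_all[, wi], k, ws$p, n_used * (ws$grid$w - ws$p))
      meas <- ddtf(m, ws$freqs, ws$fs)
      arr[, , wi, ] <- meas$ddtf
      if (measure == "all") {
        extra$dtf[, , wi, ] <- meas$dtf
        extra$ffdtf[, , wi, ] <- meas$ffdtf
        extra$pcoh[, , wi, ] <- meas$pcoh
      }
    }
  }
  if (!all(is.finite(arr))) abort_data("non-finite causality values")
  structure(arr,
    measure = "ddtf", freqs = ws$freqs, centers_s = ws$grid$centers_s,
    companions = extra, class = "ercnet_causality_map"
  )
}
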