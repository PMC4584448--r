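# Event-related causality: baseline-normalized dDTF in decibels, and the
# ternary maps of significant condition contrasts.

#' Baseline medians of a causality map
#'
#' Per (sink, source, frequency): the median of the causality values
#' over the baseline windows.
#'
#' @param map A causality array k x k x windows x freqs
#'   (an `ercnet_causality_map`).
#' @param baseline_windows Integer window indices inside the baseline
#'   period.
#' @return Array k x k x freqs of medians.
#' @export
baseline_median <- function(map, baseline_windows) {
  d <- dim(map)
  if (length(baseline_windows) < 1 ||
      any(baseline_windows < 1) || any(baseline_windows > d[3])) {
    abort_config("baseline windows outside the window grid")
  }
  sub <- aperm(map[, , baseline_windows, , drop = FALSE], c(1, 2, 4, 3))
  x <- matrix(sub, ncol = length(baseline_windows))
  array(row_medians(x), d[c(1, 2, 4)])
}

# medians of each row via one global order() call (hot path: called per
# bootstrap resample)
row_medians <- function(x) {
  nb <- ncol(x)
  if (nb == 1) return(x[, 1])
  n <- nrow(x)
  s <- matrix(x[order(rep.int(seq_len(n), nb), x)], n, nb, byrow = TRUE)
  if (nb %% 2 == 1) s[, (nb + 1) / 2] else (s[, nb / 2] + s[, nb / 2 + 1]) / 2
}

#' Event-related causality (dB)
#'
#' `ERC(t, f) = 10 * log10(dDTF(t, f) / dDTF_baseline(f))`: causality
#' expressed in decibels relative to the median of the baseline period
#' at the same frequency. Zero or negative medians are floored at
#' `eps` with a warning, since the ratio is undefined at zero.
#'
#' @param map Causality array k x k x windows x freqs.
#' @param medians Baseline medians from [baseline_median()].
#' @param eps Floor for the medians (and the numerator).
#' @return Array of the same shape as `map`, in dB.
#' @export
erc <- function(map, medians, eps = 1e-12) {
  d <- dim(map)
  if (!all(dim(medians) == d[c(1, 2, 4)])) {
    abort_config("medians shape must match (sink, source, freq) of the map")
  }
  if (any(medians <= 0)) {
    warn("baseline medians at or below zero floored for the dB ratio")
  }
  erc_quiet(map, medians, eps)
}

erc_quiet <- function(map, medians, eps = 1e-12) {
  d <- dim(map)
  medians <- pmax(medians, eps)
  med_full <- aperm(array(medians, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  10 * log10(pmax(unclass(map), eps) / med_full)
}

# ERC array for a trial index multiset (bootstrap draws pass duplicates);
# the compiled one-pass route is the default, the R route ("r") is the
# cross-checked reference
erc_for_trials <- function(ws, idx, baseline_windows) {
  counts <- tabulate(idx, nbins = ws$n_trials)
  if ((ws$engine %||% "cpp") == "cpp") {
    nz <- which(counts != 0)
    g_all <- matrix(ws$gram[, nz, drop = FALSE] %*% counts[nz],
                    ws$nfeat, ws$grid$n_windows)
    arr <- .erc_from_gram_cpp(g_all, ws$k, ws$p,
                              sum(counts) * (ws$grid$w - ws$p),
                              ws$freqs, ws$fs,
                              as.integer(baseline_windows), 1e-12)
    array(arr, c(ws$k, ws$k, ws$grid$n_windows, length(ws$freqs)))
  } else {
    map <- map_from_counts(ws, counts, engine = "r")
    med <- baseline_median(map, baseline_windows)
    erc_quiet(map, med)
  }
}

off_diagonal_mask <- function(k, n_windows, n_bins) {
  m <- array(TRUE, c(k, k, n_windows, n_bins))
  for (i in seq_len(k)) m[i, i, , ] <- FALSE
  m
}

#' Ternary map of significant ERC differences between two trial types
#'
#' Trial-level bootstrap: each type's trial set is resampled with
#' replacement, dDTF and ERC are recomputed from the resampled ensemble
#' (baseline medians included), and the per-cell difference
#' distribution yields a two-sided percentile p-value. Benjamini-
#' Hochberg correction is applied across all cells of the comparison
#' (connections x windows x frequencies); surviving cells keep the sign
#' of the observed difference.
#'
#' @param ws A causality workspace built by [build_workspace()] (or the
#'   internal `causality_workspace()`), carrying the per-trial Gram
#'   cache, window grid and frequency grid.
#' @param type_a,type_b Trial-type labels (minuend, subtrahend).
#' @param baseline_windows Window indices of the baseline period.
#' @param alpha_fdr FDR threshold.
#' @param n_boot Bootstrap resamples.
#' @param seed Optional seed.
#' @return An `ercnet_delta_erc`: tibble of nonzero cells (`sink`,
#'   `source`, `window`, `bin`, `sign`) with attributes `dims`
#'   (k, k, windows, bins), `alpha_fdr`, `comparison`, `n_cells`.
#' @export
delta_erc <- function(ws, type_a, type_b, baseline_windows,
                      alpha_fdr = 0.05, n_boot = 200, seed = NULL) {
  pairs <- tibble::tibble(
    label = paste0(type_a, "-", type_b), type_a = type_a, type_b = type_b
  )
  contrast_engine(ws, pairs, baseline_windows, alpha_fdr, n_boot, seed)[[1]]
}

#' All eighteen condition contrasts for one subject
#'
#' Runs the [delta_erc()] bootstrap for every row of
#' [build_comparisons()] against the workspace's trial types
#' (`"<scenario>.<condition>"`). All comparisons share each bootstrap
#' round's per-type ERC recomputation.
#'
#' @inheritParams delta_erc
#' @param comparisons A tibble from [build_comparisons()].
#' @return Named list of `ercnet_delta_erc`, one per comparison.
#' @export
erc_contrasts <- function(ws, baseline_windows,
                          comparisons = build_comparisons(),
                          alpha_fdr = 0.05, n_boot = 200, seed = NULL) {
  pairs <- tibble::tibble(
    label = comparisons$comparison,
    type_a = paste0(comparisons$minuend, ".", comparisons$condition),
    type_b = paste0(comparisons$subtrahend, ".", comparisons$condition)
  )
  contrast_engine(ws, pairs, baseline_windows, alpha_fdr, n_boot, seed)
}

# sign arrays (k x k x W x F per comparison) without the tibble wrapper;
# the fast path for the shuffle-inference loop
contrast_sign_arrays <- function(ws, pairs, baseline_windows, alpha_fdr,
                                 n_boot) {
  types_used <- unique(c(pairs$type_a, pairs$type_b))
  idx <- lapply(types_used, function(ty) which(ws$types == ty))
  names(idx) <- types_used
  if (any(lengths(idx) < 20)) {
    abort_data("every compared trial type needs >= 20 trials")
  }
  obs <- lapply(idx, function(ii) erc_for_trials(ws, ii, baseline_windows))
  off <- off_diagonal_mask(ws$k, ws$grid$n_windows, length(ws$freqs))
  n_pairs <- nrow(pairs)
  pos <- matrix(0, sum(off), n_pairs)
  neg <- matrix(0, sum(off), n_pairs)
  for (b in seq_len(n_boot)) {
    reps <- lapply(idx, function(ii) {
      erc_for_trials(ws, sample(ii, replace = TRUE), baseline_windows)[off]
    })
    for (j in seq_len(n_pairs)) {
      dd <- reps[[pairs$type_a[j]]] - reps[[pairs$type_b[j]]]
      pos[, j] <- pos[, j] + (dd > 0)
      neg[, j] <- neg[, j] + (dd < 0)
    }
  }
  d <- dim(obs[[1]])
  lapply(seq_len(n_pairs), function(j) {
    p_adj <- stats::p.adjust(pmin(2 * pmin(pos[, j], neg[, j]) / n_boot, 1),
                             method = "BH")
    obs_d <- obs[[pairs$type_a[j]]][off] - obs[[pairs$type_b[j]]][off]
    out <- array(0, d)
    out[off] <- sign(obs_d) * (p_adj <= alpha_fdr)
    out
  })
}

# dense ternary tensor (18 x WF x conn) straight from the workspaces;
# identical to as.array(assemble_tensor(erc_contrasts(...))) and
# cross-checked against it in the tests
contrast_tensor <- function(ws_list, baseline_windows, comparisons,
                            alpha_fdr, n_boot) {
  pairs <- tibble::tibble(
    type_a = paste0(comparisons$minuend, ".", comparisons$condition),
    type_b = paste0(comparisons$subtrahend, ".", comparisons$condition)
  )
  blocks <- lapply(ws_list, function(ws) {
    arrs <- contrast_sign_arrays(ws, pairs, baseline_windows, alpha_fdr,
                                 n_boot)
    k <- ws$k
    keep_cols <- setdiff(seq_len(k * k), seq(1, k * k, by = k + 1))
    do.call(rbind, lapply(arrs, function(a) {
      m <- matrix(aperm(a, c(3, 4, 1, 2)), dim(a)[3] * dim(a)[4])
      # columns ordered sink fast within source, diagonal dropped
      as.vector(m[, keep_cols])
    }))
  })
  n_cmp <- nrow(comparisons)
  ws1 <- ws_list[[1]]
  wf <- ws1$grid$n_windows * length(ws1$freqs)
  out <- array(0, c(n_cmp, wf,
                    sum(vapply(blocks, function(b) ncol(b) / wf, 0))))
  at <- 0
  for (b in blocks) {
    n_conn <- ncol(b) / wf
    out[, , at + seq_len(n_conn)] <- array(b, c(n_cmp, wf, n_conn))
    at <- at + n_conn
  }
  out
}

contrast_engine <- function(ws, pairs, baseline_windows, alpha_fdr,
                            n_boot, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  types_used <- unique(c(pairs$type_a, pairs$type_b))
  idx <- lapply(types_used, function(ty) which(ws$types == ty))
  names(idx) <- types_used
  n_per <- lengths(idx)
  if (any(n_per < 20)) {
    abort_data(sprintf(
      "every compared trial type needs >= 20 trials (worst: %s with %d)",
      types_used[which.min(n_per)], min(n_per)))
  }
  obs <- lapply(idx, function(ii) erc_for_trials(ws, ii, baseline_windows))
  off <- off_diagonal_mask(ws$k, ws$grid$n_windows, length(ws$freqs))
  n_cells <- sum(off)
  n_pairs <- nrow(pairs)
  pos <- matrix(0, n_cells, n_pairs)
  neg <- matrix(0, n_cells, n_pairs)
  for (b in seq_len(n_boot)) {
    reps <- lapply(idx, function(ii) {
      erc_for_trials(ws, sample(ii, replace = TRUE), baseline_windows)[off]
    })
    for (j in seq_len(n_pairs)) {
      dd <- reps[[pairs$type_a[j]]] - reps[[pairs$type_b[j]]]
      pos[, j] <- pos[, j] + (dd > 0)
      neg[, j] <- neg[, j] + (dd < 0)
    }
  }
  d <- dim(obs[[1]])
  cells <- which(off)
  out <- vector("list", n_pairs)
  names(out) <- pairs$label
  for (j in seq_len(n_pairs)) {
    p <- 2 * pmin(pos[, j], neg[, j]) / n_boot
    p_adj <- stats::p.adjust(pmin(p, 1), method = "BH")
    obs_d <- obs[[pairs$type_a[j]]][off] - obs[[pairs$type_b[j]]][off]
    sgn <- sign(obs_d) * (p_adj <= alpha_fdr)
    keep <- which(sgn != 0)
    ai <- arrayInd(cells[keep], d)
    tb <- tibble::tibble(
      sink = ai[, 1], source = ai[, 2], window = ai[, 3], bin = ai[, 4],
      sign = as.integer(sgn[keep])
    )
    out[[j]] <- structure(tb,
      dims = d, alpha_fdr = alpha_fdr, n_boot = n_boot,
      comparison = pairs$label[j], n_cells = n_cells,
      class = c("ercnet_delta_erc", class(tb))
    )
  }
  out
}
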