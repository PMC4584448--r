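# Shuffle-based significance of comparison loadings, activation-level
# reconstruction, and inter-structure dependency correlations.

# least-squares mode-1 loadings given fixed modes 2 and 3
refit_mode1 <- function(x, model) {
  if (inherits(x, "ercnet_delta_tensor")) x <- as.array(x)
  B <- model$loadings$time_frequency
  C <- model$loadings$connection
  Z <- khatri_rao(C, B)
  unfold_tensor(x, 1) %*% Z %*% solve_sym(crossprod(B) * crossprod(C))
}

#' Shuffle-test significance of the comparison loadings
#'
#' The trial-type labels are permuted within each perception condition,
#' the full dDTF, ERC, significant-contrast and tensor pipeline is
#' recomputed, and only the mode-1 (comparison) loadings are refitted
#' by least squares against the original model's fixed time-frequency
#' and connection modes. An observed loading is significant when its
#' two-sided permutation p-value `2 * min(#\{null <= obs\},
#' #\{null >= obs\} + 1) / (n_shuffles + 1)` is at or below `alpha`;
#' with 50 shuffles the achievable two-sided floor is `2/51 ~ 0.039`,
#' which is recorded on the result.
#'
#' @param ws_list Named list (per subject) of causality workspaces from
#'   [build_workspace()].
#' @param model The fitted `ercnet_parafac` supplying the fixed
#'   time-frequency and connection modes.
#' @param baseline_windows Baseline window indices.
#' @param tensor The unshuffled tensor; the observed loadings are its
#'   mode-1 refit against the fixed modes (at the ALS fixed point this
#'   equals the model's own loadings). When `NULL` the tensor is
#'   rebuilt from `ws_list` with the same contrast settings.
#' @param comparisons Comparison registry.
#' @param alpha_fdr,n_boot Contrast-stage parameters (match the
#'   original tensor build).
#' @param n_shuffles Number of label permutations.
#' @param alpha Per-loading significance level.
#' @param seed Integer seed.
#' @return An `ercnet_loading_significance` tibble: per (structure,
#'   comparison) the observed loading, null range, p-value and flag;
#'   attributes `alpha`, `alpha_floor`, `n_shuffles`.
#' @export
loading_significance <- function(ws_list, model, baseline_windows,
                                 tensor = NULL,
                                 comparisons = build_comparisons(),
                                 alpha_fdr = 0.05, n_boot = 200,
                                 n_shuffles = 50, alpha = 0.05,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_shuffles < 1 / alpha - 1) {
    warn(sprintf(
      "%d shuffles cannot resolve alpha = %g (need >= %d)",
      n_shuffles, alpha, ceiling(1 / alpha - 1)))
  }
  if (is.null(tensor)) {
    tensor <- contrast_tensor(ws_list, baseline_windows, comparisons,
                              alpha_fdr, n_boot)
  }
  observed <- refit_mode1(tensor, model)
  r <- model$r
  null_arr <- array(NA_real_, c(nrow(observed), r, n_shuffles))
  for (sh in seq_len(n_shuffles)) {
    shuffled <- lapply(ws_list, function(ws) {
      ws$types <- shuffle_types_within_condition(ws$types)
      ws
    })
    tens <- contrast_tensor(shuffled, baseline_windows, comparisons,
                            alpha_fdr, n_boot)
    null_arr[, , sh] <- refit_mode1(tens, model)
  }
  lo <- apply(null_arr, c(1, 2), min)
  hi <- apply(null_arr, c(1, 2), max)
  n_le <- apply(sweep(null_arr, c(1, 2), observed, "-") <= 0, c(1, 2), sum)
  n_ge <- apply(sweep(null_arr, c(1, 2), observed, "-") >= 0, c(1, 2), sum)
  p <- 2 * pmin(n_le + 1, n_ge + 1) / (n_shuffles + 1)
  out <- tidyr::expand_grid(
    structure = seq_len(r),
    comparison = comparisons$comparison
  )
  out <- out[order(out$structure), ]
  ij <- cbind(match(out$comparison, comparisons$comparison), out$structure)
  out$observed <- observed[ij]
  out$null_lo <- lo[ij]
  out$null_hi <- hi[ij]
  out$p_value <- pmin(p[ij], 1)
  out$significant <- out$p_value <= alpha
  out <- dplyr::left_join(
    out, comparisons[, c("comparison", "family", "minuend", "subtrahend",
                         "condition")],
    by = "comparison")
  structure(out,
    alpha = alpha, alpha_floor = 2 / (n_shuffles + 1),
    n_shuffles = n_shuffles,
    class = c("ercnet_loading_significance", class(out))
  )
}

# permute scenario labels among trials of the same condition
shuffle_types_within_condition <- function(types) {
  lab <- as.character(types)
  cond <- sub("^.*\\.", "", lab)
  for (cd in unique(cond)) {
    sel <- which(cond == cd)
    lab[sel] <- lab[sel][sample.int(length(sel))]
  }
  factor(lab, levels = levels(types))
}

#' Reconstruct per-scenario activation levels
#'
#' For each structure and condition, solves the least-squares system
#' `level(minuend) - level(subtrahend) = loading` over the significant
#' comparisons only, anchored to mean zero (the minimum-norm solution).
#' Scenarios untouched by any significant comparison stay at zero; with
#' no significant comparisons all levels are zero.
#'
#' @param sig An `ercnet_loading_significance`.
#' @return A tibble (`structure`, `condition`, `scenario`, `level`).
#' @export
reconstruct_activation <- function(sig) {
  scen <- unique(paste0(rep(contexts(), each = 2), responses()))
  out <- list()
  for (st in unique(sig$structure)) {
    for (cd in conditions()) {
      rows <- sig[sig$structure == st & sig$condition == cd &
                    sig$significant, ]
      lv <- setNames(numeric(6), scen)
      if (nrow(rows)) {
        D <- matrix(0, nrow(rows), 6, dimnames = list(NULL, scen))
        D[cbind(seq_len(nrow(rows)), match(rows$minuend, scen))] <- 1
        D[cbind(seq_len(nrow(rows)), match(rows$subtrahend, scen))] <- -1
        sol <- drop(pinv(D) %*% rows$observed)
        lv[] <- sol - mean(sol)
      }
      out[[length(out) + 1]] <- tibble::tibble(
        structure = st, condition = cd, scenario = scen, level = unname(lv)
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Correlations between structures' activation dependences
#'
#' For each comparison family (context under Rf, context under Rn,
#' response), correlates the six relevant comparison loadings (three
#' comparisons from each of the two conditions) between every pair of
#' structures, with two-sided p-values for the null of zero
#' correlation (n = 6).
#'
#' @param model An `ercnet_parafac` (needs the comparison registry; a
#'   plain fit uses the canonical [build_comparisons()] order).
#' @param comparisons Comparison registry.
#' @return A list per family: `rho` (R x R), `p_value` (R x R),
#'   `significant` logical matrix at alpha = 0.05.
#' @export
interdependency <- function(model, comparisons = build_comparisons()) {
  A <- model$loadings$comparison
  if (model$r < 2) abort_config("need at least two structures")
  fams <- unique(comparisons$family)
  out <- lapply(fams, function(fm) {
    sel <- which(comparisons$family == fm)
    X <- A[sel, , drop = FALSE] # 6 loadings x R
    zero_var <- apply(X, 2, sd) == 0
    rho <- suppressWarnings(stats::cor(X))
    p <- matrix(NA_real_, model$r, model$r)
    for (i in seq_len(model$r)) {
      for (j in seq_len(model$r)) {
        if (zero_var[i] || zero_var[j]) next
        p[i, j] <- stats::cor.test(X[, i], X[, j])$p.value
      }
    }
    list(rho = rho, p_value = p,
         significant = !is.na(p) & p < 0.05,
         zero_variance = zero_var)
  })
  names(out) <- fams
  out
}
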