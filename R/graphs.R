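# Structure-level connectivity statistics: per-subject directed graphs
# from the mode-3 loadings, node strengths, channel projection, area
# flow, top-connection overlap, and cross-fit structure matching.

area_levels <- function() c("V", "P", "PF", "mPF", "M", "aT", "pT")

#' Per-subject directed graphs from the connection loadings
#'
#' Splits every mode-3 column into its subject blocks and reshapes each
#' block into a nonnegative weight matrix over that subject's retained
#' components (`[source, sink]`, zero diagonal).
#'
#' @param model An `ercnet_parafac` fitted on an assembled tensor (the
#'   connection axis registry is required).
#' @param axes Optional axis registry list (overrides `model$axes`).
#' @return Nested list: `graphs[[structure]][[subject]]` weight matrix.
#' @export
loadings_to_graphs <- function(model, axes = model$axes) {
  if (is.null(axes$connection)) {
    abort_config("model carries no connection axis registry")
  }
  ax <- axes$connection
  C <- model$loadings$connection
  if (nrow(ax) != nrow(C)) {
    abort_data("connection registry length does not match mode-3 loadings")
  }
  subjects <- unique(ax$subject)
  lapply(seq_len(model$r), function(r) {
    out <- lapply(subjects, function(s) {
      sel <- ax$subject == s
      k <- max(ax$source[sel])
      g <- matrix(0, k, k)
      g[cbind(ax$source[sel], ax$sink[sel])] <- C[ax$index[sel], r]
      g
    })
    names(out) <- subjects
    out
  })
}

#' Node strengths of a structure graph
#'
#' Causal density is the sum of outward and inward link weights
#' (out-strength + in-strength); causal outflow is their difference.
#'
#' @param g Weight matrix `[source, sink]`, nonnegative, zero diagonal.
#' @return A tibble (`node`, `out_strength`, `in_strength`, `density`,
#'   `outflow`).
#' @export
node_strengths <- function(g) {
  out_s <- rowSums(g)
  in_s <- colSums(g)
  tibble::tibble(
    node = seq_len(nrow(g)),
    out_strength = out_s,
    in_strength = in_s,
    density = out_s + in_s,
    outflow = out_s - in_s
  )
}

#' Project per-component values to channels
#'
#' Spatially weights a per-component statistic (density, outflow) by
#' the absolute mixing weights, each component's weight profile
#' normalized to peak 1 over channels:
#' `value_ch = sum_ic |W_ic,ch| / max_ch'|W_ic,ch'| * value_ic`.
#'
#' @param values Numeric vector, one value per component.
#' @param mixing Channels x components mixing-weight matrix.
#' @return Numeric vector over channels.
#' @export
project_to_channels <- function(values, mixing) {
  if (length(values) != ncol(mixing)) {
    abort_config("one value per mixing column required")
  }
  a <- abs(mixing)
  peaks <- apply(a, 2, max)
  if (any(peaks <= 0)) abort_data("component with all-zero channel weights")
  drop(sweep(a, 2, peaks, "/") %*% values)
}

#' Maximum flow between cortical areas
#'
#' Entry (A, B) is the maximum link weight over all edges whose source
#' component lies in area A and sink component in area B; the diagonal
#' is excluded. Areas with no assigned components yield zero rows and
#' columns and are flagged.
#'
#' @param g Weight matrix `[source, sink]`.
#' @param areas Character vector mapping each node to one of the seven
#'   area codes (V, P, PF, mPF, M, aT, pT).
#' @return 7 x 7 matrix with an `empty_areas` attribute.
#' @export
area_max_flow <- function(g, areas) {
  lv <- area_levels()
  areas <- as.character(areas)
  if (length(areas) != nrow(g)) abort_config("one area per node required")
  if (!all(areas %in% lv)) abort_config("unknown area code")
  if (length(unique(areas)) < 2) abort_data("need components in >= 2 areas")
  out <- matrix(0, 7, 7, dimnames = list(lv, lv))
  for (a in unique(areas)) {
    for (b in unique(areas)) {
      if (a == b) next
      sub <- g[areas == a, areas == b, drop = FALSE]
      if (length(sub)) out[a, b] <- max(sub)
    }
  }
  attr(out, "empty_areas") <- setdiff(lv, unique(areas))
  out
}

# logical mask of the top-q strongest positive edges
top_connection_mask <- function(g, q) {
  pos <- g[g > 0 & row(g) != col(g)]
  if (!length(pos)) abort_data("graph has no positive weights")
  thr <- quantile(pos, 1 - q, type = 7, names = FALSE)
  g > thr & row(g) != col(g)
}

#' Shared fraction of top connections between two structures
#'
#' The top set of a graph holds the directed edges whose weight exceeds
#' the `(1 - q)` quantile of its positive weights. The returned ratio
#' is `|top_A intersect top_B| / |top_A|` (asymmetric: the denominator
#' counts the first structure's top connections).
#'
#' @param g_a,g_b Weight matrices over the same node set.
#' @param q Top fraction (0.10 = top 10 percent).
#' @return Shared ratio in `[0, 1]`.
#' @export
top_shared_connections <- function(g_a, g_b, q = 0.10) {
  if (!all(dim(g_a) == dim(g_b))) abort_config("graphs must share a node set")
  ta <- top_connection_mask(g_a, q)
  tb <- top_connection_mask(g_b, q)
  sum(ta & tb) / sum(ta)
}

#' Undirected pathways shared across structures
#'
#' For each quantile, an undirected edge (unordered node pair) is in a
#' structure's top set when either direction is; the function reports,
#' per pair, how many structures contain it and whether all do.
#'
#' @param graphs List of weight matrices (one per structure) over a
#'   common node set.
#' @param q Vector of top fractions.
#' @return A tibble (`q`, `node_a`, `node_b`, `n_structures`,
#'   `shared_all`).
#' @export
undirected_pathways <- function(graphs, q = c(0.01, 0.05, 0.10, 0.25)) {
  if (length(graphs) < 2) abort_config("need >= 2 graphs")
  k <- nrow(graphs[[1]])
  out <- list()
  for (qq in q) {
    masks <- lapply(graphs, function(g) {
      m <- top_connection_mask(g, qq)
      m | t(m)
    })
    counts <- Reduce(`+`, masks)
    ut <- which(upper.tri(counts) & counts > 0, arr.ind = TRUE)
    if (nrow(ut)) {
      out[[length(out) + 1]] <- tibble::tibble(
        q = qq, node_a = ut[, 1], node_b = ut[, 2],
        n_structures = counts[ut],
        shared_all = counts[ut] == length(graphs)
      )
    }
  }
  if (length(out)) dplyr::bind_rows(out) else {
    tibble::tibble(q = numeric(), node_a = integer(), node_b = integer(),
                   n_structures = integer(), shared_all = logical())
  }
}

#' Temporal and spectral profiles of each structure
#'
#' The temporal profile sums each structure's time-frequency loadings
#' across frequency bins per window; the spectral profile averages them
#' across windows per bin. Both inherit nonnegativity from the mode-2
#' constraint.
#'
#' @param model An `ercnet_parafac` with a time-frequency axis registry
#'   (or supply `n_windows`/`n_bins`).
#' @param n_windows,n_bins Grid size when the model has no registry.
#' @return A list: `temporal` (windows x R), `spectral` (bins x R).
#' @export
profiles <- function(model, n_windows = model$n_windows %||% NULL,
                     n_bins = NULL) {
  B <- model$loadings$time_frequency
  if (is.null(n_windows) && !is.null(model$axes$time_frequency)) {
    n_windows <- max(model$axes$time_frequency$window)
  }
  if (is.null(n_windows)) abort_config("window count unknown; pass n_windows")
  n_bins <- n_bins %||% (nrow(B) / n_windows)
  if (n_windows * n_bins != nrow(B)) {
    abort_config("windows x bins must equal the mode-2 length")
  }
  temporal <- matrix(0, n_windows, model$r)
  spectral <- matrix(0, n_bins, model$r)
  for (r in seq_len(model$r)) {
    m <- matrix(B[, r], n_windows, n_bins)
    temporal[, r] <- rowSums(m)
    spectral[, r] <- colMeans(m)
  }
  list(temporal = temporal, spectral = spectral)
}

#' Match and correlate structures between two fits
#'
#' Pearson correlations between the structures of two PARAFAC fits in
#' up to four domains — comparison loadings, temporal profile, spectral
#' profile, and causal outflow over all components concatenated across
#' subjects — plus the one-to-one assignment maximizing the summed
#' diagonal correlation, with significance (alpha = 0.05) and
#' high-correlation (rho > 0.8) flags.
#'
#' @param model_a,model_b `ercnet_parafac` fits with equal `r`. The
#'   outflow domain needs both to carry compatible connection
#'   registries.
#' @return An `ercnet_structure_match`: `correlations` (list of R x R
#'   matrices per domain), `assignment` (columns of `model_b` matched
#'   to each structure of `model_a`), `matched` tibble with per-domain
#'   diagonal correlations and flags.
#' @export
compare_structures <- function(model_a, model_b) {
  if (model_a$r != model_b$r) abort_config("fits have different component numbers")
  doms <- list()
  doms$comparison <- list(model_a$loadings$comparison,
                          model_b$loadings$comparison)
  pa <- profiles(model_a); pb <- profiles(model_b)
  if (nrow(pa$temporal) == nrow(pb$temporal)) {
    doms$temporal <- list(pa$temporal, pb$temporal)
  }
  if (nrow(pa$spectral) == nrow(pb$spectral)) {
    doms$spectral <- list(pa$spectral, pb$spectral)
  }
  if (!is.null(model_a$axes$connection) && !is.null(model_b$axes$connection)) {
    of <- function(m) {
      gs <- loadings_to_graphs(m)
      vapply(gs, function(per_subj) {
        unlist(lapply(per_subj, function(g) node_strengths(g)$outflow))
      }, numeric(sum(vapply(gs[[1]], nrow, 0))))
    }
    oa <- of(model_a); ob <- of(model_b)
    if (nrow(oa) == nrow(ob)) doms$outflow <- list(oa, ob)
  }
  if (length(doms) < 2) abort_data("fits share no comparable domains")

  cors <- lapply(doms, function(d) {
    cr <- suppressWarnings(stats::cor(d[[1]], d[[2]]))
    cr[!is.finite(cr)] <- 0 # constant columns carry no evidence
    cr
  })
  total <- Reduce(`+`, cors)
  assignment <- match_columns(total)
  r <- model_a$r
  rows <- lapply(names(doms), function(nm) {
    d <- doms[[nm]]
    n <- nrow(d[[1]])
    diag_r <- cors[[nm]][cbind(seq_len(r), assignment)]
    p <- vapply(seq_len(r), function(i) {
      stats::cor.test(d[[1]][, i], d[[2]][, assignment[i]])$p.value
    }, 0)
    tibble::tibble(
      domain = nm, structure = seq_len(r), matched = assignment,
      rho = diag_r, p_value = p,
      significant = p < 0.05, high = diag_r > 0.8
    )
  })
  structure(
    list(
      correlations = cors,
      assignment = assignment,
      matched = dplyr::bind_rows(rows)
    ),
    class = "ercnet_structure_match"
  )
}

#' @export
print.ercnet_structure_match <- function(x, ...) {
  cat("<ercnet_structure_match> assignment:",
      paste(seq_along(x$assignment), "->", x$assignment, collapse = ", "), "\n")
  print(x$matched)
  invisible(x)
}
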