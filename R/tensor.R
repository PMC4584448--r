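# Assembly of the 3-way comparison tensor:
#   mode 1 comparison-condition (18), mode 2 time-frequency
#   (windows x bins, window index varying fastest), mode 3
#   connection-subject (ordered source->sink pairs, sink varying
#   fastest, subject blocks concatenated).

#' Assemble the ternary comparison tensor
#'
#' Pools the significant-difference maps from all comparisons,
#' conditions, connections and subjects into one 3-way tensor with a
#' deterministic axis ordering. Entries are in {-1, 0, +1}; the tensor
#' is stored sparsely and densified on demand (`as.array()`).
#'
#' @param delta_maps Named list (one element per subject) of named
#'   lists of `ercnet_delta_erc` objects keyed by comparison label
#'   (all 18 labels of [build_comparisons()] must be present).
#' @param comparisons The comparison registry tibble.
#' @return An `ercnet_delta_tensor`: `dims`, `axes` (tibbles
#'   `comparison`, `time_frequency`, `connection`), `entries`
#'   (tibble `i`, `j`, `l`, `value`).
#' @export
assemble_tensor <- function(delta_maps, comparisons = build_comparisons()) {
  subjects <- names(delta_maps)
  if (is.null(subjects) || any(!nzchar(subjects))) {
    abort_config("`delta_maps` must be a named list of subjects")
  }
  missing <- unlist(lapply(subjects, function(s) {
    gaps <- setdiff(comparisons$comparison, names(delta_maps[[s]]))
    if (length(gaps)) paste0(s, ": ", paste(gaps, collapse = ", "))
  }))
  if (length(missing)) {
    abort_data(paste0("missing comparisons\n", paste(missing, collapse = "\n")))
  }

  first <- delta_maps[[1]][[comparisons$comparison[1]]]
  d1 <- attr(first, "dims")
  n_windows <- d1[3]; n_bins <- d1[4]
  ks <- vapply(subjects, function(s) {
    attr(delta_maps[[s]][[comparisons$comparison[1]]], "dims")[1]
  }, 0)
  for (s in subjects) {
    for (cm in comparisons$comparison) {
      dd <- attr(delta_maps[[s]][[cm]], "dims")
      if (dd[3] != n_windows || dd[4] != n_bins) {
        abort_data("subjects/comparisons disagree on the window or bin grid")
      }
    }
  }

  axes <- list(
    comparison = dplyr::mutate(comparisons, index = dplyr::row_number()),
    time_frequency = tibble::tibble(
      index = seq_len(n_windows * n_bins),
      window = rep(seq_len(n_windows), n_bins),
      bin = rep(seq_len(n_bins), each = n_windows)
    ),
    connection = dplyr::bind_rows(lapply(seq_along(subjects), function(si) {
      k <- ks[si]
      grid <- expand.grid(sink = seq_len(k), source = seq_len(k))
      grid <- grid[grid$sink != grid$source, ]
      # enumerate source-major (sink varying fastest)
      grid <- grid[order(grid$source, grid$sink), ]
      tibble::tibble(subject = subjects[si], source = grid$source,
                     sink = grid$sink)
    }))
  )
  axes$connection$index <- seq_len(nrow(axes$connection))
  offsets <- c(0, cumsum(ks * (ks - 1)))
  names(offsets) <- c(subjects, "_end")

  ent <- list()
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    k <- ks[si]
    for (ci in seq_len(nrow(comparisons))) {
      m <- delta_maps[[s]][[comparisons$comparison[ci]]]
      if (!nrow(m)) next
      within <- (m$source - 1) * (k - 1) + m$sink - (m$sink > m$source)
      ent[[length(ent) + 1]] <- tibble::tibble(
        i = ci,
        j = (m$bin - 1) * n_windows + m$window,
        l = offsets[si] + within,
        value = m$sign
      )
    }
  }
  entries <- if (length(ent)) dplyr::bind_rows(ent) else {
    tibble::tibble(i = integer(), j = integer(), l = integer(),
                   value = integer())
  }
  structure(
    list(
      dims = c(nrow(comparisons), n_windows * n_bins, sum(ks * (ks - 1))),
      axes = axes,
      n_windows = n_windows, n_bins = n_bins,
      subjects = subjects, k_per_subject = setNames(ks, subjects),
      entries = entries
    ),
    class = "ercnet_delta_tensor"
  )
}

#' @export
print.ercnet_delta_tensor <- function(x, ...) {
  cat(sprintf(
    "<ercnet_delta_tensor> %s (%d nonzero of %s cells; %d subject(s))\n",
    paste(x$dims, collapse = " x "), nrow(x$entries),
    format(prod(x$dims), big.mark = ","), length(x$subjects)
  ))
  invisible(x)
}

#' @export
as.array.ercnet_delta_tensor <- function(x, ...) {
  if (prod(x$dims) > 2^27) {
    abort_data("tensor too large to densify; work with the sparse entries")
  }
  arr <- array(0, x$dims)
  if (nrow(x$entries)) {
    arr[cbind(x$entries$i, x$entries$j, x$entries$l)] <- x$entries$value
  }
  arr
}

#' @export
dim.ercnet_delta_tensor <- function(x) x$dims

# label <-> flat index round trips
tf_label <- function(tensor, j) {
  tensor$axes$time_frequency[j, ]
}

connection_label <- function(tensor, l) {
  tensor$axes$connection[l, ]
}

tf_index <- function(tensor, window, bin) {
  (bin - 1) * tensor$n_windows + window
}

connection_index <- function(tensor, subject, source, sink) {
  ax <- tensor$axes$connection
  ax$index[ax$subject == subject & ax$source == source & ax$sink == sink]
}
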