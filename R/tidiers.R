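#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a PARAFAC fit into a long tibble of loadings
#'
#' @param x An `ercnet_parafac`.
#' @param ... Unused.
#' @return A tibble (`mode`, `index`, `structure`, `loading`) with
#'   comparison labels joined when the fit carries an axis registry.
#' @method tidy ercnet_parafac
#' @export
tidy.ercnet_parafac <- function(x, ...) {
  modes <- c("comparison", "time_frequency", "connection")
  out <- dplyr::bind_rows(lapply(modes, function(m) {
    L <- x$loadings[[m]]
    tibble::tibble(
      mode = m,
      index = rep(seq_len(nrow(L)), x$r),
      structure = rep(seq_len(x$r), each = nrow(L)),
      loading = as.vector(L)
    )
  }))
  if (!is.null(x$axes$comparison)) {
    lab <- x$axes$comparison
    out$label <- NA_character_
    sel <- out$mode == "comparison"
    out$label[sel] <- lab$comparison[out$index[sel]]
  }
  out
}

#' One-row summary of a PARAFAC fit
#'
#' @param x An `ercnet_parafac`.
#' @param ... Unused.
#' @return A tibble with `r`, `fit`, `iterations`, `converged`, `init`.
#' @method glance ercnet_parafac
#' @export
glance.ercnet_parafac <- function(x, ...) {
  tibble::tibble(
    r = x$r, fit = x$fit, iterations = x$iterations,
    converged = x$converged, init = x$init
  )
}

#' Tidy a ternary contrast map
#'
#' @param x An `ercnet_delta_erc`.
#' @param ... Unused.
#' @return A plain tibble of the nonzero cells with the comparison
#'   label attached.
#' @method tidy ercnet_delta_erc
#' @export
tidy.ercnet_delta_erc <- function(x, ...) {
  out <- tibble::as_tibble(unclass(x)[c("sink", "source", "window", "bin",
                                        "sign")])
  out$comparison <- attr(x, "comparison")
  out
}

#' Plot the loadings of a PARAFAC fit
#'
#' One panel per mode: signed comparison loadings as bars, the
#' nonnegative time-frequency and connection loadings as line profiles,
#' colored by structure.
#'
#' @param object An `ercnet_parafac`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ercnet_parafac
#' @export
autoplot.ercnet_parafac <- function(object, ...) {
  df <- tidy(object)
  df$structure <- factor(df$structure)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$loading,
                                   colour = .data$structure)) +
    ggplot2::geom_line(data = df[df$mode != "comparison", ], linewidth = 0.3) +
    ggplot2::geom_col(data = df[df$mode == "comparison", ],
                      ggplot2::aes(fill = .data$structure),
                      position = "dodge", width = 0.8) +
    ggplot2::facet_wrap(~mode, scales = "free", ncol = 1) +
    ggplot2::labs(x = NULL, y = "loading") +
    ggplot2::theme_minimal()
}

#' Plot a core-consistency scan
#'
#' Consistency versus component number for both initialization
#' methods, with the selection threshold.
#'
#' @param object An `ercnet_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ercnet_scan
#' @export
autoplot.ercnet_scan <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$r, y = .data$corcondia,
                               colour = .data$init)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$selected_r, linetype = 3) +
    ggplot2::coord_cartesian(ylim = c(min(0, min(object$curve$corcondia)), 100)) +
    ggplot2::labs(x = "components", y = "core consistency (%)") +
    ggplot2::theme_minimal()
}

#' Plot a ternary contrast map
#'
#' Time-frequency tile map of the count of significantly stronger
#' (+1) minus weaker (-1) connections per cell.
#'
#' @param object An `ercnet_delta_erc`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ercnet_delta_erc
#' @export
autoplot.ercnet_delta_erc <- function(object, ...) {
  df <- tidy(object)
  agg <- dplyr::summarise(
    dplyr::group_by(df, .data$window, .data$bin),
    net = sum(.data$sign), .groups = "drop"
  )
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$window, y = .data$bin,
                                    fill = .data$net)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "window", y = "frequency bin",
                  fill = "net +/-",
                  title = attr(object, "comparison")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
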