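# Synthetic ground truth: latent AR(2) resonator sources with scheduled,
# condition-dependent cross-couplings.
#
# Each source is a damped resonator (resonance frequency = band center,
# damping set by bandwidth), so a lagged linear coupling from a source
# transfers band-limited power to its sink. A schedule entry switches a
# directed coupling on during a trial-relative interval, with a gain per
# trial type (context x response x condition) that encodes the planted
# context/response dependence.

#' Source resonator specification
#'
#' @param resonance_hz Per-source resonance frequencies (Hz).
#' @param bandwidth_hz Per-source half-power bandwidths (Hz); sets the
#'   pole damping `rho = exp(-pi * bw / fs)`.
#' @return A tibble with one row per source.
#' @export
source_spec <- function(resonance_hz = c(80, 25, 15, 6, 10, 6),
                        bandwidth_hz = rep(8, length(resonance_hz))) {
  tibble::tibble(
    source = seq_along(resonance_hz),
    resonance_hz = resonance_hz,
    bandwidth_hz = bandwidth_hz
  )
}

#' Default planted-effect specification
#'
#' Five condition-dependent couplings mirroring the kinds of latent
#' structures the analysis is designed to find:
#' \enumerate{
#'   \item context-graded beta coupling during Context (Cm > Ch > Cw),
#'   \item Rf-only high-gamma coupling during Response,
#'   \item generalized-context beta coupling during Context (Ch = Cm > Cw),
#'   \item its Rf-gated, Cplus-only re-activation during Response,
#'   \item a reversed-direction alpha/low-beta coupling during Response
#'     (the top-down reversal of the first structure's pair), gated on
#'     Cplus and Rf with the generalized context dependence.
#' }
#' The three Response-period couplings activate sequentially
#' (perception, then retrieval, then top-down modulation), so at most
#' one coupling drives any sink in a given segment: each segment's
#' coupling graph is acyclic (stability follows from the resonator
#' poles) and the normalization built into the directed spectral
#' measures cannot smear one coupling's contrast across another's
#' connections.
#' Gains are multipliers on the coupling strength per trial type.
#'
#' @param strength Base lag-1 coupling coefficient (unitless).
#' @return A list of effect entries (used by [build_schedule()]).
#' @export
default_effect_spec <- function(strength = 0.35) {
  gain_tbl <- function(f) {
    tt <- trial_types()
    setNames(vapply(seq_len(nrow(tt)), function(i) {
      f(tt$context[i], tt$response[i], tt$condition[i])
    }, 0), tt$type)
  }
  list(
    list(
      name = "context_graded_context", family = "context",
      source = 2, sink = 4, band_hz = 25, from_s = 2.5, to_s = 3.5,
      strength = strength,
      gain = gain_tbl(function(cx, rs, cd) {
        g <- c(Ch = 0.55, Cm = 1, Cw = 0)[[cx]]
        g * c(Cplus = 1, Cminus = 0.5)[[cd]]
      })
    ),
    list(
      name = "response_perception", family = "response",
      source = 1, sink = 6, band_hz = 80, from_s = 4.0, to_s = 5.0,
      strength = strength,
      gain = gain_tbl(function(cx, rs, cd) as.numeric(rs == "Rf"))
    ),
    list(
      name = "generalized_context", family = "context",
      source = 3, sink = 5, band_hz = 15, from_s = 3.0, to_s = 4.0,
      strength = strength,
      gain = gain_tbl(function(cx, rs, cd) {
        g <- as.numeric(cx != "Cw")
        g * c(Cplus = 1, Cminus = 0.5)[[cd]]
      })
    ),
    list(
      name = "context_retrieval", family = "context",
      source = 3, sink = 5, band_hz = 15, from_s = 5.0, to_s = 6.0,
      strength = strength,
      gain = gain_tbl(function(cx, rs, cd) {
        as.numeric(cx != "Cw" && rs == "Rf" && cd == "Cplus")
      })
    ),
    list(
      name = "topdown_feedback", family = "response",
      source = 5, sink = 2, band_hz = 10, from_s = 6.0, to_s = 7.0,
      strength = strength,
      gain = gain_tbl(function(cx, rs, cd) {
        as.numeric(rs == "Rf" && cd == "Cplus")
      })
    )
  )
}

#' Build a stable coupling schedule
#'
#' Assembles the time-varying VAR implied by the resonator sources plus
#' the requested coupling entries and verifies stability (companion
#' spectral radius < 1) in every piecewise-constant segment of every
#' trial type. Unstable requests are rejected with a report.
#'
#' @param effects List of effect entries (see [default_effect_spec()]);
#'   an empty list gives baseline-only dynamics.
#' @param sources A [source_spec()] tibble.
#' @param timeline A [task_timeline()].
#' @param fs Sampling rate (Hz) the schedule will be simulated at.
#' @return An `ercnet_schedule`: entries tibble, per-type segment
#'   coefficient tables, source parameters.
#' @export
#' @examples
#' sched <- build_schedule(default_effect_spec(), fs = 250)
#' sched
build_schedule <- function(effects = default_effect_spec(),
                           sources = source_spec(),
                           timeline = task_timeline(), fs = 250) {
  nyq <- fs / 2
  k <- nrow(sources)
  if (any(sources$resonance_hz >= nyq) || any(sources$resonance_hz <= 0)) {
    abort_config("source resonances must lie within (0, Nyquist)")
  }
  entries <- if (length(effects)) {
    dplyr::bind_rows(lapply(effects, function(e) {
      tibble::tibble(
        name = e$name %||% NA_character_,
        family = e$family %||% NA_character_,
        source = e$source, sink = e$sink,
        band_hz = e$band_hz, strength = e$strength,
        from_s = e$from_s, to_s = e$to_s,
        gain = list(e$gain)
      )
    }))
  } else {
    tibble::tibble(
      name = character(), family = character(),
      source = integer(), sink = integer(),
      band_hz = numeric(), strength = numeric(),
      from_s = numeric(), to_s = numeric(), gain = list()
    )
  }
  if (nrow(entries)) {
    if (any(entries$source == entries$sink)) {
      abort_config("self-couplings are not allowed")
    }
    if (any(entries$band_hz >= nyq) || any(entries$band_hz <= 0)) {
      abort_config("coupling bands must lie within (0, Nyquist)")
    }
    if (any(entries$from_s < 0) || any(entries$to_s > timeline$trial_length) ||
        any(entries$from_s >= entries$to_s)) {
      abort_config("coupling intervals must lie within the trial")
    }
    if (any(entries$source > k | entries$sink > k)) {
      abort_config("entry references a source beyond the source spec")
    }
  }
  sched <- structure(
    list(entries = entries, sources = sources, timeline = timeline, fs = fs),
    class = "ercnet_schedule"
  )
  report <- schedule_stability(sched)
  if (any(report$radius >= 1)) {
    bad <- report[report$radius >= 1, ]
    abort_config(
      paste0(
        "unstable schedule: companion spectral radius >= 1 in ",
        nrow(bad), " segment(s); worst: type ", bad$type[which.max(bad$radius)],
        sprintf(" radius %.3f", max(bad$radius))
      ),
      report = report
    )
  }
  attr(sched, "stability") <- report
  sched
}

#' @export
print.ercnet_schedule <- function(x, ...) {
  cat(sprintf(
    "<ercnet_schedule> %d coupling entries over %d sources @ %g Hz (max companion radius %.3f)\n",
    nrow(x$entries), nrow(x$sources), x$fs,
    if (nrow(attr(x, "stability"))) max(attr(x, "stability")$radius) else NA
  ))
  if (nrow(x$entries)) {
    print(x$entries[, c("name", "source", "sink", "band_hz", "strength",
                        "from_s", "to_s")])
  }
  invisible(x)
}

# resonator AR(2) diagonal terms; innovation SDs chosen so every
# uncoupled source has unit stationary variance (keeps the channel
# covariance spectrum balanced for the variance-based ICA order rule)
resonator_coefs <- function(sources, fs) {
  rho <- exp(-pi * sources$bandwidth_hz / fs)
  theta <- 2 * pi * sources$resonance_hz / fs
  a1 <- 2 * rho * cos(theta)
  a2 <- -rho^2
  gamma0 <- (1 - a2) / ((1 + a2) * ((1 - a2)^2 - a1^2))
  list(a1 = a1, a2 = a2, innov_sd = 1 / sqrt(gamma0))
}

# piecewise-constant lag-1 coefficient matrices per trial type
# returns list(per type: list(breaks_s, A1 = list per segment), A2)
schedule_segments <- function(sched) {
  k <- nrow(sched$sources)
  res <- resonator_coefs(sched$sources, sched$fs)
  A1_base <- diag(res$a1, k)
  A2 <- diag(res$a2, k)
  tt <- trial_types()
  per_type <- lapply(seq_len(nrow(tt)), function(ti) {
    ty <- tt$type[ti]
    ent <- sched$entries
    breaks <- sort(unique(c(0, sched$timeline$trial_length,
                            pmax(pmin(c(ent$from_s, ent$to_s),
                                      sched$timeline$trial_length), 0))))
    segs <- lapply(seq_len(length(breaks) - 1), function(si) {
      mid <- (breaks[si] + breaks[si + 1]) / 2
      A1 <- A1_base
      if (nrow(ent)) {
        for (ei in seq_len(nrow(ent))) {
          g <- ent$gain[[ei]][[ty]]
          if (!is.null(g) && g != 0 && mid >= ent$from_s[ei] && mid < ent$to_s[ei]) {
            A1[ent$sink[ei], ent$source[ei]] <-
              A1[ent$sink[ei], ent$source[ei]] + ent$strength[ei] * g
          }
        }
      }
      A1
    })
    list(breaks = breaks, A1 = segs)
  })
  names(per_type) <- tt$type
  list(per_type = per_type, A2 = A2)
}

# stability of every (type, segment): companion spectral radius
schedule_stability <- function(sched) {
  segs <- schedule_segments(sched)
  rows <- list()
  for (ty in names(segs$per_type)) {
    s <- segs$per_type[[ty]]
    for (si in seq_along(s$A1)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        type = ty, from_s = s$breaks[si], to_s = s$breaks[si + 1],
        radius = companion_radius(list(s$A1[[si]], segs$A2))
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Expected contrast pattern of each planted structure
#'
#' For every schedule entry and every one of the 18 comparisons, the
#' sign of the gain difference `gain(minuend) - gain(subtrahend)`: the
#' direction in which the planted coupling should move the measured
#' causality contrast. This is the generator-truth reference the
#' recovered comparison loadings are matched against.
#'
#' @param sched An `ercnet_schedule`.
#' @param comparisons Comparison registry.
#' @return Matrix 18 x n_entries of {-1, 0, +1}, columns named by
#'   entry.
#' @export
planted_contrast_pattern <- function(sched,
                                     comparisons = build_comparisons()) {
  ent <- sched$entries
  if (!nrow(ent)) abort_config("schedule has no planted entries")
  out <- matrix(0, nrow(comparisons), nrow(ent),
                dimnames = list(comparisons$comparison, ent$name))
  for (ei in seq_len(nrow(ent))) {
    g <- ent$gain[[ei]]
    ty_a <- paste0(comparisons$minuend, ".", comparisons$condition)
    ty_b <- paste0(comparisons$subtrahend, ".", comparisons$condition)
    out[, ei] <- sign(unlist(g[ty_a]) - unlist(g[ty_b]))
  }
  out
}

#' Planted reference model for structure matching
#'
#' Builds a PARAFAC-shaped reference from the generator truth: mode-1
#' columns are the planted contrast patterns, mode-2 columns indicate
#' each entry's active windows with a Gaussian profile over frequency
#' bins centred on the coupling band, and mode-3 columns put unit
#' weight on the planted connection (per subject). Recovered fits are
#' matched against this reference with [compare_structures()].
#'
#' @param sched An `ercnet_schedule`.
#' @param tensor An `ercnet_delta_tensor` (supplies axes and grids).
#' @param grid The window grid used for the causality maps.
#' @param freqs Frequency-bin centers (Hz).
#' @param source_map Optional mapping from planted source index to the
#'   component index in each subject's retained basis; defaults to
#'   identity (valid when the analysis runs on the true sources).
#' @return An `ercnet_parafac`-shaped reference model.
#' @export
planted_reference <- function(sched, tensor, grid, freqs,
                              source_map = NULL) {
  ent <- sched$entries
  if (!nrow(ent)) abort_config("schedule has no planted entries")
  R <- nrow(ent)
  A <- planted_contrast_pattern(sched)
  n_w <- tensor$n_windows
  n_b <- tensor$n_bins
  B <- matrix(0, n_w * n_b, R)
  for (ei in seq_len(R)) {
    act <- grid$centers_s >= ent$from_s[ei] & grid$centers_s < ent$to_s[ei]
    bw <- sched$sources$bandwidth_hz[ent$source[ei]]
    fw <- exp(-(freqs - ent$band_hz[ei])^2 / (2 * bw^2))
    B[, ei] <- as.vector(outer(as.numeric(act), fw))
  }
  ax <- tensor$axes$connection
  C <- matrix(0, nrow(ax), R)
  for (ei in seq_len(R)) {
    for (s in tensor$subjects) {
      map <- if (is.null(source_map)) identity else source_map[[s]]
      src <- if (is.function(map)) map(ent$source[ei]) else map[ent$source[ei]]
      snk <- if (is.function(map)) map(ent$sink[ei]) else map[ent$sink[ei]]
      if (is.na(src) || is.na(snk)) next
      C[ax$subject == s & ax$source == src & ax$sink == snk, ei] <- 1
    }
  }
  structure(
    list(
      loadings = list(comparison = A, time_frequency = B, connection = C),
      r = R, dims = tensor$dims, fit = NA_real_,
      init = "planted", axes = tensor$axes, n_windows = n_w
    ),
    class = "ercnet_parafac"
  )
}

#' Planted VAR model at a trial time
#'
#' The exact VAR coefficients the generator uses for a given trial type
#' at a given trial-relative time. This is the analytic oracle for
#' recoverability checks: spectral measures computed from these
#' coefficients are the ground truth the estimation pipeline should
#' approach.
#'
#' @param sched An `ercnet_schedule`.
#' @param type Trial-type label (see [trial_types()]).
#' @param time_s Trial-relative time in seconds.
#' @return An `ercnet_var` with the planted coefficients and unit
#'   innovation covariance.
#' @export
planted_var <- function(sched, type, time_s) {
  segs <- schedule_segments(sched)
  s <- segs$per_type[[type]]
  if (is.null(s)) abort_config(sprintf("unknown trial type '%s'", type))
  si <- findInterval(time_s, s$breaks, rightmost.closed = TRUE)
  si <- min(max(si, 1L), length(s$A1))
  sd_i <- resonator_coefs(sched$sources, sched$fs)$innov_sd
  new_var_model(list(s$A1[[si]], segs$A2), diag(sd_i^2))
}
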