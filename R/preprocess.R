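# Trial screening, artifact-trial rejection, decimation, line-noise
# removal, and the three-step local stationarization.

#' Classify trials by gaze into perception conditions
#'
#' A trial is `Cplus` when the gaze position lies inside the screen area
#' strictly more than `threshold` of the time during the screening
#' window (the first 0.5 s of the Context period by default); samples
#' with invalid gaze (eyes closed, out of recording range: non-finite
#' coordinates) count as off-screen.
#'
#' @param rec An `ercnet_recording` with gaze traces.
#' @param threshold On-screen fraction that must be strictly exceeded.
#' @param window `[start, end]` screening window in trial-relative
#'   seconds; defaults to the first 0.5 s of Context.
#' @return A tibble (`trial`, `fraction`, `condition`).
#' @export
screen_condition <- function(rec, threshold = 0.8, window = NULL) {
  if (is.null(rec$gaze)) abort_data("recording carries no gaze traces")
  tl <- rec$timeline
  window <- window %||% c(tl$context_on, tl$context_on + 0.5)
  if (window[1] < 0 || window[2] > tl$trial_length || window[1] >= window[2]) {
    abort_config("screening window must lie within the trial")
  }
  fs_g <- attr(rec$gaze, "fs") %||% 30
  bounds <- attr(rec$gaze, "on_screen") %||% list(x = c(0, 1), y = c(0, 1))
  n_trials <- dim(rec$data)[1]
  fractions <- vapply(seq_len(n_trials), function(tr) {
    g <- rec$gaze[[tr]]
    if (is.null(g)) abort_data(sprintf("trial %d has no gaze trace", tr))
    tt <- (seq_len(nrow(g)) - 0.5) / fs_g
    sel <- tt >= window[1] & tt < window[2]
    if (!any(sel)) abort_data(sprintf("trial %d: no gaze samples in window", tr))
    gs <- g[sel, , drop = FALSE]
    on <- is.finite(gs[, 1]) & is.finite(gs[, 2]) &
      gs[, 1] >= bounds$x[1] & gs[, 1] <= bounds$x[2] &
      gs[, 2] >= bounds$y[1] & gs[, 2] <= bounds$y[2]
    mean(on)
  }, 0)
  tibble::tibble(
    trial = seq_len(n_trials),
    fraction = fractions,
    condition = ifelse(fractions > threshold, "Cplus", "Cminus")
  )
}

#' Apply a screening report to a recording's labels
#'
#' Replaces the condition (and hence trial-type) labels with the
#' screened ones.
#'
#' @param rec An `ercnet_recording`.
#' @param report A tibble from [screen_condition()].
#' @return The recording with updated labels.
#' @export
apply_screening <- function(rec, report = screen_condition(rec)) {
  rec$labels$condition <- report$condition[match(rec$labels$trial, report$trial)]
  rec$labels$type <- paste0(rec$labels$scenario, ".", rec$labels$condition)
  rec
}

default_artifact_bands <- function() {
  list(c(1, 4), c(4, 8), c(8, 30), c(30, 80), c(80, 120))
}

#' Reject trials with abnormal spectra
#'
#' Per trial and channel, band-averaged log spectral power is computed
#' in a fixed band set; a trial is removed when any channel's band
#' power deviates from the cross-trial median by more than `z_threshold`
#' robust z-units (median/MAD) in any band. The cross-trial reference
#' is taken within each trial type when every type has at least 10
#' trials (so genuine condition-dependent power differences are not
#' mistaken for artifacts), and across all trials otherwise. Bands are
#' clipped to the Nyquist frequency.
#'
#' @param rec An `ercnet_recording` (>= 10 trials).
#' @param z_threshold Robust-z rejection threshold.
#' @param bands List of `c(lo, hi)` Hz band edges.
#' @param group_by_type Compare each trial against its own trial type's
#'   ensemble when group sizes allow.
#' @return A list: `recording` (kept trials), `kept` (indices),
#'   `report` (tibble of removed trials with channel, band, z).
#' @export
reject_artifact_trials <- function(rec, z_threshold = 4,
                                   bands = default_artifact_bands(),
                                   group_by_type = TRUE) {
  d <- dim(rec$data)
  n_trials <- d[1]; n_ch <- d[2]; n_samp <- d[3]
  if (n_trials < 10) abort_data("artifact rejection needs >= 10 trials")
  bands <- lapply(bands, function(b) c(b[1], min(b[2], rec$fs / 2)))
  bands <- bands[vapply(bands, function(b) b[2] > b[1], TRUE)]
  fgrid <- (seq_len(floor(n_samp / 2)) ) * rec$fs / n_samp
  band_idx <- lapply(bands, function(b) which(fgrid >= b[1] & fgrid < b[2]))
  keep_band <- lengths(band_idx) > 0
  bands <- bands[keep_band]; band_idx <- band_idx[keep_band]

  # log band power per trial x channel x band
  bp <- array(0, c(n_trials, n_ch, length(bands)))
  for (tr in seq_len(n_trials)) {
    x <- matrix(rec$data[tr, , ], n_ch)
    pw <- Mod(stats::mvfft(t(x)))^2 / n_samp
    for (bi in seq_along(bands)) {
      bp[tr, , bi] <- log(colMeans(pw[band_idx[[bi]] + 1, , drop = FALSE]) +
                            .Machine$double.eps)
    }
  }
  groups <- if (group_by_type && !is.null(rec$labels$type) &&
                min(table(rec$labels$type)) >= 10) {
    rec$labels$type
  } else {
    rep("all", n_trials)
  }
  z <- array(0, dim(bp))
  for (g in unique(groups)) {
    sel <- which(groups == g)
    for (ch in seq_len(n_ch)) {
      for (bi in seq_along(bands)) {
        z[sel, ch, bi] <- robust_z(bp[sel, ch, bi])
      }
    }
  }
  bad <- which(abs(z) > z_threshold, arr.ind = TRUE)
  removed <- unique(bad[, 1])
  if (length(removed) == n_trials) abort_data("all trials rejected")
  report <- tibble::tibble(
    trial = bad[, 1],
    channel = bad[, 2],
    band = vapply(bad[, 3], function(b) paste(bands[[b]], collapse = "-"), ""),
    z = z[bad]
  )
  kept <- setdiff(seq_len(n_trials), removed)
  list(
    recording = subset_trials(rec, kept),
    kept = kept,
    report = report
  )
}

# keep a subset of trials in a recording (indices into current order)
subset_trials <- function(rec, idx) {
  rec$data <- rec$data[idx, , , drop = FALSE]
  rec$labels <- rec$labels[idx, ]
  if (!is.null(rec$gaze)) {
    at <- attributes(rec$gaze)
    rec$gaze <- rec$gaze[idx]
    for (a in setdiff(names(at), "names")) attr(rec$gaze, a) <- at[[a]]
  }
  if (!is.null(rec$sources)) rec$sources <- rec$sources[idx, , , drop = FALSE]
  rec$artifact_trials <- intersect(rec$artifact_trials, idx)
  rec
}

#' Decimate a recording
#'
#' Zero-phase 8th-order Butterworth anti-alias filtering at 80 percent
#' of the target Nyquist, then subsampling.
#'
#' @param rec An `ercnet_recording`.
#' @param factor Integer decimation factor.
#' @return The recording at `fs / factor`.
#' @export
decimate_trials <- function(rec, factor = 4) {
  if (factor < 1 || factor != round(factor)) {
    abort_config("decimation factor must be a positive integer")
  }
  d <- dim(rec$data)
  if (floor(d[3] / factor) < 2) abort_data("too few samples after decimation")
  if (factor == 1) return(rec)
  bf <- signal::butter(8, 0.8 / factor, type = "low")
  idx <- seq(1, d[3], by = factor)
  out <- array(0, c(d[1], d[2], length(idx)))
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      y <- signal::filtfilt(bf, rec$data[tr, ch, ])
      out[tr, ch, ] <- y[idx]
    }
  }
  rec$data <- out
  rec$fs <- rec$fs / factor
  if (!is.null(rec$sources)) {
    ds <- dim(rec$sources)
    src <- array(0, c(ds[1], ds[2], length(idx)))
    for (tr in seq_len(ds[1])) {
      for (s in seq_len(ds[2])) {
        src[tr, s, ] <- signal::filtfilt(bf, rec$sources[tr, s, ])[idx]
      }
    }
    rec$sources <- src
  }
  rec
}

#' Remove power-line noise with a zero-phase IIR notch
#'
#' Second-order Butterworth band-stop of quality factor `q` applied
#' forward and backward.
#'
#' @param rec An `ercnet_recording`.
#' @param line_hz Line frequency (must be below Nyquist).
#' @param q Notch quality factor (`bandwidth = line_hz / q`).
#' @return The filtered recording.
#' @export
remove_line_noise <- function(rec, line_hz = 50, q = 35) {
  nyq <- rec$fs / 2
  if (line_hz >= nyq) abort_config("line frequency must be below Nyquist")
  bw <- line_hz / q
  bf <- signal::butter(2, c(line_hz - bw / 2, line_hz + bw / 2) / nyq,
                       type = "stop")
  d <- dim(rec$data)
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      rec$data[tr, ch, ] <- signal::filtfilt(bf, rec$data[tr, ch, ])
    }
  }
  rec
}

#' Local stationarization
#'
#' Three steps per the multitrial causality workflow: (1) detrending —
#' the best-fitting line is subtracted from each trial and channel;
#' (2) temporal normalization — each trial/channel series is z-scored;
#' (3) ensemble normalization — at every (channel, time point) the
#' cross-trial ensemble mean is subtracted and the ensemble SD divided
#' out.
#'
#' @param rec An `ercnet_recording` with >= 2 trials.
#' @return The stationarized recording.
#' @export
stationarize <- function(rec) {
  rec$data <- stationarize_array(rec$data)
  rec
}

#' Local stationarization of a plain trial array
#'
#' The same three steps as [stationarize()] applied to any
#' trials x series x samples array (used on the retained source
#' signals ahead of the sliding-window VAR stage).
#'
#' @param x Numeric array trials x series x samples, >= 2 trials.
#' @return The stationarized array.
#' @export
stationarize_array <- function(x) {
  d <- dim(x)
  if (length(d) != 3) abort_config("need a trials x series x samples array")
  if (d[1] < 2) abort_data("ensemble normalization needs >= 2 trials")
  tt <- seq_len(d[3])
  tt_c <- tt - mean(tt)
  denom <- sum(tt_c^2)
  for (tr in seq_len(d[1])) {
    xt <- matrix(x[tr, , ], d[2])
    slope <- (xt %*% tt_c) / denom
    xt <- xt - outer(drop(slope), tt_c) - rowMeans(xt)
    s <- apply(xt, 1, sd)
    if (any(s <= 0)) {
      abort_data(sprintf(
        "zero variance after detrending: trial %d channel %d",
        tr, which(s <= 0)[1]))
    }
    x[tr, , ] <- xt / s
  }
  for (ch in seq_len(d[2])) {
    xt <- matrix(x[, ch, ], d[1])
    mu <- colMeans(xt)
    s <- apply(xt, 2, sd)
    if (any(s <= 0)) {
      abort_data(sprintf(
        "zero ensemble SD: channel %d time point %d", ch, which(s <= 0)[1]))
    }
    x[, ch, ] <- sweep(sweep(xt, 2, mu), 2, s, "/")
  }
  x
}
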