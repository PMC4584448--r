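#' Sliding-window grid for local stationarity
#'
#' Segments a trial into overlapping analysis windows. Millisecond
#' lengths are converted to samples by round-half-up (e.g. 250 ms at
#' 250 Hz is 63 samples, 50 ms is 13) and the realized durations are
#' recorded. Window timestamps are window centers.
#'
#' @param n_samples Samples per trial.
#' @param fs Sampling rate in Hz.
#' @param window_ms,step_ms Window length and step in milliseconds.
#' @return An `ercnet_window_grid`: `w`, `step` (samples), `n_windows`,
#'   `starts` (1-based first sample), `centers_s`, realized durations.
#' @export
#' @examples
#' segment(2000, 250) # 150 windows of 63 samples, step 13
segment <- function(n_samples, fs, window_ms = 250, step_ms = 50) {
  w <- ms_to_samples(window_ms, fs)
  step <- ms_to_samples(step_ms, fs)
  if (w < 1 || step < 1) abort_config("window and step must be >= 1 sample")
  if (w > n_samples) abort_config("window longer than trial")
  n_windows <- floor((n_samples - w) / step) + 1L
  starts <- 1L + step * (seq_len(n_windows) - 1L)
  structure(
    list(
      w = w, step = step, n_windows = as.integer(n_windows),
      starts = starts,
      centers_s = (starts - 1 + (w - 1) / 2) / fs,
      fs = fs,
      window_ms = window_ms, step_ms = step_ms,
      realized_window_ms = 1000 * w / fs,
      realized_step_ms = 1000 * step / fs
    ),
    class = "ercnet_window_grid"
  )
}

#' @export
print.ercnet_window_grid <- function(x, ...) {
  cat(sprintf(
    "<ercnet_window_grid> %d windows of %d samples (%.1f ms), step %d (%.1f ms) @ %g Hz\n",
    x$n_windows, x$w, x$realized_window_ms, x$step, x$realized_step_ms, x$fs
  ))
  invisible(x)
}

# windows whose sample interval lies entirely inside [from, to] seconds
windows_in_interval <- function(grid, from, to) {
  t0 <- (grid$starts - 1) / grid$fs
  t1 <- (grid$starts - 1 + grid$w) / grid$fs
  which(t0 >= from & t1 <= to)
}

#' VAR sample-budget check
#'
#' A multitrial VAR with `k` channels and order `p` estimates `k^2 * p`
#' coefficients from `w * n * k` scalar samples per window. The adopted
#' rule requires the parameter count to be at most 10 percent of the
#' scalar sample count, i.e. `w * n * k >= 10 * k^2 * p`. The literal
#' one-line form `w >= 10 * k^2 * p / n` is also evaluated and a
#' disagreement between the two readings is flagged.
#'
#' @param w Window length in samples.
#' @param k Number of channels (retained sources).
#' @param p VAR model order.
#' @param n Number of trials.
#' @return A list: `pass` (adopted rule), `margin` (`w` minus the
#'   adopted minimum), `w_min`, `pass_literal`, `w_min_literal`,
#'   `readings_disagree`.
#' @export
#' @examples
#' check_sample_budget(w = 63, k = 33, p = 9, n = 122)
check_sample_budget <- function(w, k, p, n) {
  if (any(c(w, k, p, n) <= 0)) abort_config("all arguments must be positive")
  w_min <- 10 * k * p / n           # from w * n * k >= 10 * k^2 * p
  w_min_literal <- 10 * k^2 * p / n
  pass <- w >= w_min
  pass_literal <- w >= w_min_literal
  list(
    pass = pass,
    margin = w - w_min,
    w_min = w_min,
    pass_literal = pass_literal,
    w_min_literal = w_min_literal,
    readings_disagree = pass != pass_literal
  )
}

#' Linear frequency grid
#'
#' @param n_bins Number of bin centers.
#' @param from,to First and last bin center in Hz.
#' @return Numeric vector of bin centers.
#' @export
#' @examples
#' freq_grid() # 19 bins, 4 to 120 Hz
freq_grid <- function(n_bins = 19, from = 4, to = 120) {
  if (n_bins < 1 || from <= 0 || to <= from) abort_config("invalid frequency grid")
  seq(from, to, length.out = n_bins)
}
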