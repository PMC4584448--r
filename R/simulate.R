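# Trial simulation: latent sources evolve as the scheduled time-varying
# VAR, channels observe a linear mixture plus noise, gaze traces encode
# the perception condition, and a small fraction of trials carries a
# broadband artifact burst.

#' Ground truth for a synthetic subject
#'
#' @param n_channels Number of recording channels (>= number of sources).
#' @param sched An `ercnet_schedule`.
#' @param seed Integer seed (mixing matrix and everything downstream).
#' @param areas Optional named assignment of sources to cortical areas
#'   (fixture for area-level statistics); defaults to a fixed map over
#'   the seven areas used in the analysis.
#' @return An `ercnet_ground_truth`: unit-column mixing matrix
#'   (channels x sources), schedule, planted structure count, seed.
#' @export
ground_truth <- function(n_channels = 12, sched = build_schedule(),
                         seed = 1, areas = NULL) {
  k <- nrow(sched$sources)
  if (n_channels < k) {
    abort_config("need at least as many channels as sources (mixing not injective)")
  }
  set.seed(seed)
  mix <- matrix(rnorm(n_channels * k), n_channels, k)
  mix <- qr.Q(qr(mix))[, seq_len(k), drop = FALSE] # full column rank
  mix <- sweep(mix, 2, apply(mix, 2, function(co) sign(co[which.max(abs(co))])), "*")
  areas <- areas %||%
    setNames(c("V", "pT", "aT", "M", "PF", "mPF")[seq_len(min(k, 6))],
             seq_len(min(k, 6)))
  structure(
    list(
      mixing = mix, schedule = sched,
      n_structures = nrow(sched$entries), seed = seed, areas = areas
    ),
    class = "ercnet_ground_truth"
  )
}

#' Simulate a trial-segmented recording
#'
#' Sources evolve as the scheduled time-varying VAR (1 s burn-in under
#' baseline dynamics); innovation amplitudes are modulated by slow
#' log-normal envelopes (`envelope_sd`, unit mean square), making the
#' oscillations bursty as cortical band power is — and making the
#' source marginals super-Gaussian, which the ICA stage requires for
#' identifiability. Channels are the mixing matrix applied to the
#' sources plus observation noise. Each
#' trial carries a 30 Hz two-dimensional gaze trace whose on-screen
#' fraction in the screening window encodes the trial's assigned
#' condition, and a configurable fraction of trials receives a 0.5 s
#' broadband burst at `artifact_scale` times the channel SD. Identical
#' seeds give bit-identical output.
#'
#' @param truth An [ground_truth()] object.
#' @param n_trials_per_type Trials per each of the 12 trial types (>= 2).
#' @param seed Integer seed.
#' @param obs_noise_sd Observation noise SD (channel units).
#' @param envelope_sd Log-scale SD of the slow amplitude envelopes
#'   (0 disables the modulation).
#' @param envelope_hz Knot rate of the envelopes in Hz.
#' @param artifact_prob Probability a trial carries an artifact burst.
#' @param artifact_scale Burst amplitude in channel SDs.
#' @param subject Subject identifier.
#' @return An `ercnet_recording`: `data` (trials x channels x samples),
#'   `fs`, `labels` (tibble), `timeline`, `gaze` (list of n x 2
#'   matrices at 30 Hz with attribute `on_screen` bounds), `subject`,
#'   `artifact_trials`, and the generating `truth`.
#' @export
simulate_trials <- function(truth, n_trials_per_type = 120, seed = 1,
                            obs_noise_sd = 0.2, envelope_sd = 0.6,
                            envelope_hz = 4, artifact_prob = 0.05,
                            artifact_scale = 5, subject = "S1") {
  if (n_trials_per_type < 2) abort_config("need >= 2 trials per type")
  sched <- truth$schedule
  fs <- sched$fs
  tl <- sched$timeline
  n_samp <- round(tl$trial_length * fs)
  k <- nrow(sched$sources)
  n_ch <- nrow(truth$mixing)
  set.seed(seed)

  tt <- trial_types()
  labels <- tt[rep(seq_len(nrow(tt)), each = n_trials_per_type), ]
  n_trials <- nrow(labels)
  ord <- sample.int(n_trials) # randomized presentation order
  labels <- labels[ord, ]
  labels$trial <- seq_len(n_trials)

  segs <- schedule_segments(sched)
  burnin <- round(fs)
  sources <- array(0, c(n_trials, k, n_samp))
  for (ti in seq_len(nrow(tt))) {
    ty <- tt$type[ti]
    rows <- which(labels$type == ty)
    n <- length(rows)
    seg <- segs$per_type[[ty]]
    # per-sample segment membership (burn-in uses the first segment)
    seg_of <- findInterval((seq_len(n_samp) - 0.5) / fs, seg$breaks,
                           rightmost.closed = TRUE)
    seg_of <- pmin(pmax(seg_of, 1L), length(seg$A1))
    x1 <- matrix(0, k, n) # state at t-1, all trials of this type at once
    x2 <- matrix(0, k, n)
    a2 <- diag(segs$A2)
    innov_sd <- resonator_coefs(sched$sources, fs)$innov_sd
    env <- amplitude_envelopes(k, n, n_samp, fs, envelope_sd, envelope_hz)
    for (t in seq_len(burnin)) {
      x0 <- seg$A1[[1]] %*% x1 + x2 * a2 + matrix(rnorm(k * n), k) * innov_sd
      x2 <- x1; x1 <- x0
    }
    for (t in seq_len(n_samp)) {
      x0 <- seg$A1[[seg_of[t]]] %*% x1 + x2 * a2 +
        matrix(rnorm(k * n), k) * (innov_sd * env[, , t])
      sources[rows, , t] <- t(x0)
      x2 <- x1; x1 <- x0
    }
  }

  data <- array(0, c(n_trials, n_ch, n_samp))
  for (tr in seq_len(n_trials)) {
    data[tr, , ] <- truth$mixing %*% matrix(sources[tr, , ], k) +
      matrix(rnorm(n_ch * n_samp, sd = obs_noise_sd), n_ch)
  }

  # artifact bursts: 0.5 s of broadband noise on all channels
  artifact_trials <- which(runif(n_trials) < artifact_prob)
  burst_len <- round(0.5 * fs)
  for (tr in artifact_trials) {
    onset <- sample.int(n_samp - burst_len, 1)
    span <- onset:(onset + burst_len - 1)
    ch_sd <- apply(matrix(data[tr, , ], n_ch), 1, sd)
    data[tr, , span] <- data[tr, , span] +
      matrix(rnorm(n_ch * burst_len), n_ch) * (artifact_scale * ch_sd)
  }

  # gaze: targets consistent with the assigned condition, strict 0.8 rule
  frac <- ifelse(labels$condition == "Cplus", runif(n_trials, 0.9, 1),
                 runif(n_trials, 0, 0.6))
  gaze <- generate_gaze(frac, duration_s = tl$trial_length,
                        screen_window = c(tl$context_on, tl$context_on + 0.5))

  structure(
    list(
      data = data, fs = fs,
      labels = labels[, c("trial", "context", "response", "condition",
                          "scenario", "type")],
      timeline = tl, gaze = gaze, subject = subject,
      artifact_trials = artifact_trials,
      sources = sources, truth = truth
    ),
    class = "ercnet_recording"
  )
}

#' Match estimated components to the true latent sources
#'
#' Greedy one-to-one assignment on the absolute correlation between
#' estimated component series and the generator's source series.
#'
#' @param est Array trials x m x samples (estimated components).
#' @param truth Array trials x k x samples (true sources).
#' @param min_cor Matches below this absolute correlation become `NA`.
#' @return Integer vector of length k: for each true source, the index
#'   of the matching estimated component (or `NA`).
#' @export
match_sources <- function(est, truth, min_cor = 0.5) {
  m <- dim(est)[2]; k <- dim(truth)[2]
  E <- matrix(aperm(est, c(2, 3, 1)), m)
  Tr <- matrix(aperm(truth, c(2, 3, 1)), k)
  cc <- abs(stats::cor(t(Tr), t(E))) # k x m
  out <- rep(NA_integer_, k)
  avail <- seq_len(m)
  for (i in order(-apply(cc, 1, max))) {
    if (!length(avail)) break
    j <- avail[which.max(cc[i, avail])]
    if (cc[i, j] >= min_cor) {
      out[i] <- j
      avail <- setdiff(avail, j)
    }
  }
  out
}

# slow unit-mean-square log-normal amplitude envelopes, k x n x T
amplitude_envelopes <- function(k, n, n_samp, fs, envelope_sd, envelope_hz) {
  if (envelope_sd <= 0) return(array(1, c(k, n, n_samp)))
  n_knots <- max(2, ceiling(n_samp / fs * envelope_hz) + 1)
  knots_t <- seq(1, n_samp, length.out = n_knots)
  env <- array(0, c(k, n, n_samp))
  grid <- seq_len(n_samp)
  for (s in seq_len(k)) {
    for (tr in seq_len(n)) {
      z <- rnorm(n_knots)
      env[s, tr, ] <- exp(envelope_sd *
                            stats::approx(knots_t, z, xout = grid)$y -
                            envelope_sd^2)
    }
  }
  env
}

#' @export
print.ercnet_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<ercnet_recording> %s: %d trials x %d channels x %d samples @ %g Hz\n",
    x$subject, d[1], d[2], d[3], x$fs
  ))
  invisible(x)
}

#' Generate gaze traces with target on-screen fractions
#'
#' 30 Hz two-dimensional traces. The realized on-screen fraction inside
#' the screening window matches the target within one sample: exactly
#' `round(target * n_window_samples)` window samples are placed inside
#' the unit-square screen area, the rest outside.
#'
#' @param fraction_on_screen Per-trial target fractions in `[0, 1]`.
#' @param duration_s Trace duration in seconds.
#' @param screen_window `[start, end]` of the screening window in
#'   trial-relative seconds.
#' @param fs_gaze Gaze sampling rate (Hz).
#' @return A list of n x 2 matrices with attributes `fs`, `on_screen`
#'   (the unit-square bounds).
#' @export
generate_gaze <- function(fraction_on_screen, duration_s,
                          screen_window, fs_gaze = 30) {
  if (any(fraction_on_screen < 0 | fraction_on_screen > 1)) {
    abort_config("target fractions must lie in [0, 1]")
  }
  n <- round(duration_s * fs_gaze)
  win <- which((seq_len(n) - 0.5) / fs_gaze >= screen_window[1] &
                 (seq_len(n) - 0.5) / fs_gaze < screen_window[2])
  out <- lapply(fraction_on_screen, function(fr) {
    g <- matrix(0.5 + 0.3 * (runif(2 * n) - 0.5), n, 2) # inside the screen
    n_on <- round(fr * length(win))
    off <- if (n_on < length(win)) sample(win, length(win) - n_on) else integer()
    if (length(off)) g[off, ] <- cbind(1.5 + runif(length(off)), runif(length(off)))
    stray <- setdiff(which(runif(n) < 0.1), win) # occasional off-screen looks
    if (length(stray)) g[stray, 1] <- 1.2 + runif(length(stray))
    g
  })
  attr(out, "fs") <- fs_gaze
  attr(out, "on_screen") <- list(x = c(0, 1), y = c(0, 1))
  attr(out, "screen_window") <- screen_window
  out
}

#' Simulate a multi-subject study
#'
#' One recording per subject with a shared schedule but subject-specific
#' mixing matrices and trials.
#'
#' @inheritParams simulate_trials
#' @param n_subjects Number of subjects.
#' @param n_channels Channels per subject.
#' @param sched Shared coupling schedule.
#' @param seed Master seed; per-subject seeds are derived from it.
#' @return Named list of `ercnet_recording`.
#' @export
simulate_study <- function(n_subjects = 3, n_channels = 12,
                           sched = build_schedule(),
                           n_trials_per_type = 120, seed = 1, ...) {
  seeds <- derive_seeds(seed, 2 * n_subjects)
  out <- lapply(seq_len(n_subjects), function(s) {
    truth <- ground_truth(n_channels, sched, seed = seeds[2 * s - 1])
    simulate_trials(truth, n_trials_per_type, seed = seeds[2 * s],
                    subject = paste0("S", s), ...)
  })
  names(out) <- paste0("S", seq_len(n_subjects))
  out
}
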