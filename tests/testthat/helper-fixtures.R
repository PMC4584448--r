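# Shared fixtures, built once per test run and cached.

fixture_env <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- build()
  fixture_env[[name]]
}

# low-rate timeline/schedule without the high-gamma entry (fits fs = 100)
low_fs_effects <- function(strength = 0.35) {
  eff <- default_effect_spec(strength)
  for (i in seq_along(eff)) {
    if (eff[[i]]$band_hz >= 50) eff[[i]]$band_hz <- 40
  }
  eff
}

low_fs_sources <- function() {
  source_spec(resonance_hz = c(40, 25, 15, 6, 10, 6))
}

# small recording with the full default schedule at fs = 200
tiny_recording <- function() {
  cached("tiny_recording", function() {
    tl <- task_timeline(trial_length = 7)
    sched <- build_schedule(default_effect_spec(), timeline = tl, fs = 200)
    truth <- ground_truth(8, sched, seed = 421)
    simulate_trials(truth, 30, seed = 422)
  })
}

# preprocessed copy (screened labels, artifact trials rejected)
tiny_preprocessed <- function() {
  cached("tiny_preprocessed", function() {
    rec <- apply_screening(tiny_recording())
    reject_artifact_trials(rec)$recording
  })
}

# oracle workspace on the (stationarized) true sources of the tiny
# recording
tiny_workspace <- function() {
  cached("tiny_workspace", function() {
    rec <- tiny_preprocessed()
    ws <- build_workspace(stationarize_array(rec$sources),
                          rec$labels$type, rec$fs,
                          window_ms = 500, step_ms = 500,
                          freqs = seq(5, 90, length.out = 8), p = 2)
    ws$baseline <- baseline_windows(ws$grid, rec$timeline)
    ws
  })
}

# a null recording (no planted couplings) at fs = 100, 3 sources
null_recording <- function(seed, n_per_type = 2) {
  tl <- task_timeline(trial_length = 7)
  sched <- build_schedule(list(), sources = source_spec(c(20, 10, 6)),
                          timeline = tl, fs = 100)
  truth <- ground_truth(5, sched, seed = seed)
  simulate_trials(truth, n_per_type, seed = seed + 1,
                  artifact_prob = 0)
}

# empty ternary contrast map with given dimensions (axis plumbing tests)
empty_delta <- function(k, n_windows, n_bins, comparison = "x") {
  structure(
    tibble::tibble(sink = integer(), source = integer(),
                   window = integer(), bin = integer(), sign = integer()),
    dims = c(k, k, n_windows, n_bins), alpha_fdr = 0.05, n_boot = 0,
    comparison = comparison, n_cells = k * (k - 1) * n_windows * n_bins,
    class = c("ercnet_delta_erc", class(tibble::tibble()))
  )
}

# full set of 18 empty contrast maps per subject at given sizes
empty_delta_maps <- function(ks, n_windows, n_bins) {
  cmp <- build_comparisons()
  out <- lapply(ks, function(k) {
    maps <- lapply(cmp$comparison, function(cc) {
      empty_delta(k, n_windows, n_bins, cc)
    })
    names(maps) <- cmp$comparison
    maps
  })
  names(out) <- paste0("S", seq_along(ks))
  out
}

# random trilinear tensor with the PARAFAC constraint pattern
random_trilinear <- function(dims, r, noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(dims[1] * r), dims[1])
  B <- abs(matrix(rnorm(dims[2] * r), dims[2]))
  C <- abs(matrix(rnorm(dims[3] * r), dims[3]))
  B <- sweep(B, 2, sqrt(colSums(B^2)), "/")
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")
  x <- ercnet:::compose_parafac(A, B, C)
  if (noise > 0) {
    x <- x + array(rnorm(length(x), sd = noise * sqrt(mean(x^2))), dims)
  }
  list(x = x, A = A, B = B, C = C)
}

# minimal recording-shaped object for preprocessing unit tests
fake_recording <- function(data, fs, gaze = NULL, timeline = task_timeline()) {
  structure(
    list(
      data = data, fs = fs,
      labels = tibble::tibble(
        trial = seq_len(dim(data)[1]),
        context = "Cm", response = "Rf", condition = "Cplus",
        scenario = "CmRf", type = "CmRf.Cplus"
      ),
      timeline = timeline, gaze = gaze, subject = "F1",
      artifact_trials = integer()
    ),
    class = "ercnet_recording"
  )
}
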