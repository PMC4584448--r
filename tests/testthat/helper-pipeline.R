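# Desk-scale pipeline configuration used for the end-to-end recovery
# study: one synthetic subject, the default five-structure schedule at
# 200 Hz, half-second analysis windows, and seven PARAFAC components
# (the two spare components absorb the sink-normalization side lobes of
# the directed measures, which are prominent at small source counts).

recovery_config <- function(seed) {
  list(
    seed = seed,
    simulate = list(n_subjects = 1, n_channels = 8, n_trials_per_type = 36,
                    fs = 200, trial_length = 7),
    ica = list(restarts = 5, max_samples = 5e4),
    causality = list(window_ms = 700, step_ms = 700, n_bins = 8,
                     f_lo = 5, f_hi = 90, p = 2),
    erc = list(n_boot = 60),
    tensor = list(r = 7, n_init = 15),
    infer = list(n_shuffles = 50)
  )
}

# one cached full pipeline run (left behind by the recovery study, or
# built on demand when a test file runs in isolation)
get_recovery_run <- function() {
  cached("recovery_run", function() {
    suppressMessages(suppressWarnings(
      run_pipeline(recovery_config(101),
                   stages = c("simulate", "preprocess", "ica", "causality",
                              "erc", "tensor", "stats"))
    ))
  })
}

# run the full pipeline for one seed and count how many planted
# structures map (via compare_structures assignment against the
# generator-truth reference) to a recovered structure whose significant
# comparison loadings agree in sign with the planted contrast pattern
structure_recovery_score <- function(seed) {
  run <- suppressMessages(suppressWarnings(run_pipeline(recovery_config(seed))))
  # keep one full run around for the workflow smoke assertions
  if (is.null(fixture_env$recovery_run)) fixture_env$recovery_run <- run
  model <- run$artifacts$tensor$model
  tens <- run$artifacts$tensor$tensor
  rec <- run$artifacts$preprocess[[1]]
  ica <- run$artifacts$ica[[1]]
  sched <- rec$truth$schedule
  smap <- list(S1 = match_sources(kept_sources(ica), rec$sources))
  ref <- planted_reference(sched, tens, run$artifacts$causality[[1]]$grid,
                           run$artifacts$causality[[1]]$freqs,
                           source_map = smap)
  # pad the reference with zero structures so the assignment is square
  if (model$r > ref$r) {
    pad <- model$r - ref$r
    set.seed(1)
    for (mode in names(ref$loadings)) {
      filler <- matrix(abs(rnorm(nrow(ref$loadings[[mode]]) * pad, sd = 1e-6)),
                       ncol = pad)
      ref$loadings[[mode]] <- cbind(ref$loadings[[mode]], filler)
    }
    ref$r <- model$r
  }
  am <- compare_structures(model, ref)
  sig <- run$artifacts$infer$significance
  pat <- planted_contrast_pattern(sched)
  ok <- logical(ncol(pat))
  for (ei in seq_len(ncol(pat))) {
    rc <- which(am$assignment == ei)
    if (!length(rc)) next
    ss <- sig[sig$structure == rc & sig$significant, ]
    if (!nrow(ss)) next
    expected <- pat[match(ss$comparison, rownames(pat)), ei]
    ok[ei] <- mean(expected != 0 & sign(ss$observed) == expected) > 0.5
  }
  sum(ok)
}
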