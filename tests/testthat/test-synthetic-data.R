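# The synthetic-data generator: schedules, stability, trial simulation,
# gaze traces.

test_that("empty effect spec gives baseline-only dynamics", {
  sched <- build_schedule(list(), sources = source_spec(c(20, 10)),
                          fs = 100)
  expect_equal(nrow(sched$entries), 0)
  st <- attr(sched, "stability")
  expect_true(all(st$radius < 1))
  # baseline-only: every segment's lag-1 matrix is diagonal
  segs <- ercnet:::schedule_segments(sched)
  for (ty in names(segs$per_type)) {
    for (A1 in segs$per_type[[ty]]$A1) {
      expect_equal(A1, diag(diag(A1)))
    }
  }
})

test_that("default spec plants five structures with distinct signatures", {
  sched <- build_schedule(fs = 250)
  ent <- sched$entries
  expect_equal(nrow(ent), 5)
  sig <- paste(ent$band_hz, ent$from_s, ent$to_s,
               vapply(ent$gain, function(g) paste(g, collapse = ","), ""))
  expect_equal(length(unique(sig)), 5)
  expect_true(all(ent$source != ent$sink))
  expect_true(all(attr(sched, "stability")$radius < 1))
  # planted contrast patterns are pairwise distinct
  pat <- planted_contrast_pattern(sched)
  expect_equal(nrow(unique(t(pat))), 5)
})

test_that("unstable coupling strengths are rejected with a stability report", {
  two_cycle <- list(
    list(name = "fwd", source = 1, sink = 2, band_hz = 12, strength = 0.99,
         from_s = 2.5, to_s = 4, gain = setNames(as.list(rep(1, 12)),
                                                 trial_types()$type)),
    list(name = "rev", source = 2, sink = 1, band_hz = 12, strength = 0.99,
         from_s = 2.5, to_s = 4, gain = setNames(as.list(rep(1, 12)),
                                                 trial_types()$type))
  )
  src <- source_spec(c(12, 12))
  # independent oracle: assemble the coupled companion matrix directly
  rc <- ercnet:::resonator_coefs(src, 100)
  A1 <- diag(rc$a1, 2); A1[2, 1] <- 0.99; A1[1, 2] <- 0.99
  A2 <- diag(rc$a2, 2)
  comp <- rbind(cbind(A1, A2), cbind(diag(2), matrix(0, 2, 2)))
  expect_gte(max(Mod(eigen(comp, only.values = TRUE)$values)), 1)

  err <- expect_error(
    build_schedule(two_cycle, sources = src, fs = 100),
    class = "ercnet_config_error"
  )
  expect_true(any(err$report$radius >= 1))
})

test_that("invalid schedule requests are rejected", {
  g <- setNames(as.list(rep(1, 12)), trial_types()$type)
  mk <- function(...) list(list(name = "e", source = 1, sink = 2,
                                strength = 0.1, gain = g, ...))
  expect_error(build_schedule(mk(band_hz = 60, from_s = 1, to_s = 2),
                              sources = source_spec(c(20, 10)), fs = 100),
               class = "ercnet_config_error") # band beyond Nyquist
  expect_error(build_schedule(mk(band_hz = 20, from_s = 5, to_s = 99),
                              sources = source_spec(c(20, 10)), fs = 100),
               class = "ercnet_config_error") # interval outside trial
  bad_self <- list(list(name = "s", source = 1, sink = 1, band_hz = 20,
                        strength = 0.1, from_s = 1, to_s = 2, gain = g))
  expect_error(build_schedule(bad_self, sources = source_spec(c(20, 10)),
                              fs = 100),
               class = "ercnet_config_error")
})

test_that("simulation is bit-identical under a fixed seed", {
  rec1 <- null_recording(31, n_per_type = 2)
  rec2 <- null_recording(31, n_per_type = 2)
  expect_identical(rec1$data, rec2$data)
  expect_identical(rec1$labels, rec2$labels)
  expect_identical(rec1$gaze, rec2$gaze)
})

test_that("fewer channels than sources is rejected", {
  sched <- build_schedule(list(), sources = source_spec(c(20, 10, 6)),
                          fs = 100)
  expect_error(ground_truth(2, sched), class = "ercnet_config_error")
})

test_that("uncoupled sources have near-unit variance", {
  tl <- task_timeline(trial_length = 7)
  sched <- build_schedule(list(), sources = source_spec(c(20, 10, 6)),
                          timeline = tl, fs = 100)
  truth <- ground_truth(5, sched, seed = 77)
  rec <- simulate_trials(truth, 4, seed = 78, artifact_prob = 0,
                         envelope_sd = 0) # amplitude modulation off
  v <- vapply(seq_len(dim(rec$sources)[2]), function(s) {
    var(as.vector(rec$sources[, s, ]))
  }, 0)
  expect_true(all(abs(v - 1) < 0.15))
})

test_that("planted couplings are recoverable from the analytic transfer", {
  sched <- build_schedule(fs = 250)
  fr <- freq_grid()
  # generalized-context coupling s3 -> s5 at 15 Hz, active late Context
  m <- planted_var(sched, "CmRf.Cplus", 3.5)
  meas <- ddtf(m, fr, 250)
  band <- which.min(abs(fr - 15))
  expect_gte(meas$ddtf[5, 3, band], 3 * meas$ddtf[3, 5, band])
  # top-down coupling s5 -> s2 at 10 Hz in Response, Cplus Rf only
  m2 <- planted_var(sched, "CmRf.Cplus", 5.0)
  band2 <- which.min(abs(fr - 10))
  meas2 <- ddtf(m2, fr, 250)
  expect_gte(meas2$ddtf[2, 5, band2], 3 * meas2$ddtf[5, 2, band2])
  # same link is silent for Rn trials
  m3 <- planted_var(sched, "CmRn.Cplus", 5.0)
  expect_lt(ddtf(m3, fr, 250)$ddtf[2, 5, band2], 1e-10)
})

test_that("gaze traces hit their on-screen targets and the strict 0.8 rule", {
  set.seed(9)
  tl <- task_timeline(trial_length = 7)
  win <- c(tl$context_on, tl$context_on + 0.5)
  gz <- generate_gaze(c(1, 0, 0.79, 12 / 15), duration_s = 7,
                      screen_window = win)
  rec <- fake_recording(array(0, c(4, 2, 700)), fs = 100, gaze = gz,
                        timeline = tl)
  rep <- screen_condition(rec)
  expect_equal(rep$condition, c("Cplus", "Cminus", "Cminus", "Cminus"))
  # realized fraction within one sample of the target
  expect_true(all(abs(rep$fraction - c(1, 0, 0.79, 0.8)) <= 1 / 15 + 1e-9))
  expect_error(generate_gaze(1.2, 7, win), class = "ercnet_config_error")
})

test_that("artifact trials carry visible broadband bursts", {
  tl <- task_timeline(trial_length = 7)
  sched <- build_schedule(list(), sources = source_spec(c(20, 10, 6)),
                          timeline = tl, fs = 100)
  truth <- ground_truth(5, sched, seed = 3)
  rec <- simulate_trials(truth, 4, seed = 4, artifact_prob = 0.3)
  expect_gt(length(rec$artifact_trials), 0)
  clean <- setdiff(seq_len(dim(rec$data)[1]), rec$artifact_trials)
  peak <- function(tr) max(abs(rec$data[tr, 1, ]))
  expect_gt(median(sapply(rec$artifact_trials, peak)),
            median(sapply(clean, peak)))
})
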