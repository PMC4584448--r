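# Sliding windows, sample budget, multitrial VAR, model validation,
# spectral transfer, and the DTF family.

test_that("window segmentation follows the count invariant", {
  g <- segment(2000, 250, 250, 50)
  expect_equal(g$w, 63) # 250 ms at 250 Hz, round half up
  expect_equal(g$step, 13)
  expect_equal(g$n_windows, floor((2000 - 63) / 13) + 1)
  expect_equal(g$n_windows, 150)
  expect_equal(segment(500, 250, 2000, 50)$n_windows, 1) # w = T
  expect_equal(segment(100, 100, 500, 900)$n_windows, 1) # step > T - w
  expect_error(segment(100, 250, 2000, 50), class = "ercnet_config_error")
})

test_that("the sample budget reports both readings", {
  b <- check_sample_budget(w = 63, k = 33, p = 9, n = 122)
  expect_true(b$pass)
  expect_equal(b$w_min, 10 * 33 * 9 / 122, tolerance = 1e-12)
  expect_false(b$pass_literal)
  expect_true(b$readings_disagree)
  b1 <- check_sample_budget(w = 63, k = 33, p = 9, n = 1)
  expect_false(b1$pass)
  bk <- check_sample_budget(w = 63, k = 1, p = 5, n = 10)
  expect_equal(bk$w_min, bk$w_min_literal) # k = 1: readings coincide
  expect_error(check_sample_budget(0, 1, 1, 1), class = "ercnet_config_error")
})

test_that("AIC recovers planted orders and stays minimal on noise", {
  set.seed(51)
  A1 <- diag(0.5, 3); A1[2, 1] <- 0.4
  A2 <- diag(-0.3, 3)
  A3 <- diag(0.15, 3)
  m3 <- ercnet:::new_var_model(list(A1, A2, A3), diag(3))
  x <- ercnet:::simulate_var_trials(m3, 250, 80)
  sel <- select_order_aic(x, 6)
  expect_equal(sel$p, 3)
  expect_true(all(is.finite(sel$aic$aic)))
  wn <- array(rnorm(250 * 3 * 80), c(250, 3, 80))
  expect_equal(select_order_aic(wn, 5)$p, 1)
  expect_error(select_order_aic(wn[1:2, , ], 60),
               class = "ercnet_config_error") # budget violation
})

test_that("multitrial least squares recovers planted coefficients", {
  set.seed(52)
  A1 <- matrix(0, 3, 3); diag(A1) <- 0.5; A1[2, 1] <- 0.4; A1[3, 2] <- -0.3
  A2 <- diag(-0.25, 3)
  truth <- ercnet:::new_var_model(list(A1, A2), diag(3))
  x <- ercnet:::simulate_var_trials(truth, 200, 60)
  fit <- fit_var_multitrial(x, 2)
  expect_lt(max(abs(fit$A[[1]] - A1)), 0.05)
  expect_lt(max(abs(fit$A[[2]] - A2)), 0.05)
  # uncoupled: off-diagonals near zero
  xd <- ercnet:::simulate_var_trials(
    ercnet:::new_var_model(list(diag(0.6, 3)), diag(3)), 200, 60)
  fd <- fit_var_multitrial(xd, 1)
  off <- fd$A[[1]][row(A1) != col(A1)]
  expect_lt(max(abs(off)), 0.05)
})

test_that("model validation behaves on its own simulation and on random walks", {
  set.seed(53)
  A1 <- matrix(c(0.5, 0.3, 0, 0.4), 2)
  truth <- ercnet:::new_var_model(list(A1), diag(2))
  x <- ercnet:::simulate_var_trials(truth, 80, 60)
  fit <- fit_var_multitrial(x, 1)
  v <- validate_var(fit, x)
  expect_true(v$whiteness$pass)
  expect_gte(v$consistency$percent, 95)
  expect_true(v$consistency$pass)
  expect_gte(v$stationary, 0.5)
  # whiteness holds across repeated windows of self-simulated data
  passes <- replicate(10, {
    xs <- ercnet:::simulate_var_trials(fit, 60, 50)
    validate_var(fit_var_multitrial(xs, 1), xs)$whiteness$pass
  })
  expect_gte(mean(passes), 0.9)
  # random walk: KPSS rejects stationarity
  rw <- array(t(apply(matrix(rnorm(20 * 300), 20), 1, cumsum)), c(20, 1, 300))
  expect_false(kpss_level(colMeans(rw[, 1, ]))$pass)
})

test_that("the spectral transfer matches closed forms", {
  null_model <- ercnet:::new_var_model(list(matrix(0, 2, 2)), diag(2))
  H <- spectral_transfer(null_model, c(5, 20, 45), 100)
  for (i in 1:3) expect_equal(H[, , i], diag(2) + 0i)

  # hand-written 2x2 VAR(1): symbolic inverse oracle
  A <- matrix(c(0.5, 0.2, -0.1, 0.3), 2)
  m <- ercnet:::new_var_model(list(A), diag(2))
  f <- 12; fs <- 100
  z <- exp(-2i * pi * f / fs)
  Af <- diag(2) - A * z
  det_a <- Af[1, 1] * Af[2, 2] - Af[1, 2] * Af[2, 1]
  H_oracle <- matrix(c(Af[2, 2], -Af[2, 1], -Af[1, 2], Af[1, 1]), 2) / det_a
  expect_lt(max(Mod(spectral_transfer(m, f, fs)[, , 1] - H_oracle)), 1e-10)

  # AR(2) resonator: |H| peaks at the planted resonance within one bin
  src <- source_spec(25, 6)
  rc <- ercnet:::resonator_coefs(src, 250)
  mr <- ercnet:::new_var_model(list(matrix(rc$a1, 1, 1), matrix(rc$a2, 1, 1)),
                               matrix(1))
  grid <- seq(5, 60, by = 1)
  mag <- Mod(spectral_transfer(mr, grid, 250)[1, 1, ])
  expect_lte(abs(grid[which.max(mag)] - 25), 2)
  expect_error(spectral_transfer(m, 60, 100), class = "ercnet_config_error")
})

test_that("dDTF suppresses indirect paths and obeys its normalizations", {
  A1 <- matrix(0, 3, 3); diag(A1) <- 0.5; A1[2, 1] <- 0.5; A1[3, 2] <- 0.5
  truth <- ercnet:::new_var_model(list(A1, diag(-0.3, 3)), diag(3))
  fr <- seq(2, 45, length.out = 12)
  meas <- ddtf(truth, fr, 100)
  # uncoupled pair: nothing flows 2 -> 1
  expect_lt(max(meas$ddtf[1, 2, ]), 1e-10)
  # indirect path 1 -> 3 via 2: DTF sees it, dDTF suppresses it
  expect_gt(max(meas$dtf[3, 1, ]), 0.1)
  expect_lt(max(meas$ddtf[3, 1, ]), 0.2 * max(meas$dtf[3, 1, ]))
  # ffDTF normalization per sink
  expect_lt(max(abs(apply(meas$ffdtf^2, 1, sum) - 1)), 1e-8)
  # all measures within [0, 1]; dDTF below ffDTF
  for (nm in names(meas)) {
    expect_true(all(meas[[nm]] >= 0 & meas[[nm]] <= 1 + 1e-12))
  }
  expect_true(all(meas$ddtf <= meas$ffdtf + 1e-12))
  # diagonal-only model: off-diagonal dDTF identically zero
  dm <- ercnet:::new_var_model(list(diag(0.5, 3)), diag(3))
  md <- ddtf(dm, fr, 100)
  offdiag <- md$ddtf[rep(row(diag(3)) != col(diag(3)), length(fr))]
  expect_lt(max(offdiag), 1e-10)
})

test_that("ffDTF normalization holds on random stable VARs", {
  set.seed(54)
  fr <- seq(2, 45, length.out = 10)
  for (i in 1:5) {
    repeat {
      A1 <- matrix(rnorm(16, sd = 0.3), 4)
      A2 <- matrix(rnorm(16, sd = 0.15), 4)
      if (ercnet:::companion_radius(list(A1, A2)) < 0.95) break
    }
    S <- crossprod(matrix(rnorm(16), 4)) / 4 + diag(0.1, 4)
    meas <- ddtf(ercnet:::new_var_model(list(A1, A2), S), fr, 100)
    expect_lt(max(abs(apply(meas$ffdtf^2, 1, sum) - 1)), 1e-8)
  }
})

test_that("directionality: planted one-way links estimated from data", {
  set.seed(55)
  A1 <- matrix(0, 3, 3); diag(A1) <- 0.5; A1[2, 1] <- 0.5
  truth <- ercnet:::new_var_model(list(A1, diag(-0.3, 3)), diag(3))
  x <- ercnet:::simulate_var_trials(truth, 120, 80)
  fit <- fit_var_multitrial(x, 2)
  fr <- seq(2, 45, length.out = 12)
  est <- ddtf(fit, fr, 100)
  tru <- ddtf(truth, fr, 100)
  expect_lt(max(est$ddtf[1, 2, ]), 0.33 * max(est$ddtf[2, 1, ]))
  # estimated in-band causality close to the analytic value
  band <- which.max(tru$ddtf[2, 1, ])
  expect_lt(abs(est$ddtf[2, 1, band] - tru$ddtf[2, 1, band]) /
              tru$ddtf[2, 1, band], 0.15)
})

test_that("the compiled and reference causality routes agree exactly", {
  ws <- tiny_workspace()
  counts <- as.numeric(ws$types == "CmRf.Cplus")
  m_cpp <- ercnet:::map_from_counts(ws, counts, measure = "all",
                                    engine = "cpp")
  m_r <- ercnet:::map_from_counts(ws, counts, measure = "all", engine = "r")
  expect_lt(max(abs(m_cpp - m_r)), 1e-12)
  for (nm in c("dtf", "ffdtf", "pcoh")) {
    expect_lt(max(abs(attr(m_cpp, "companions")[[nm]] -
                        attr(m_r, "companions")[[nm]])), 1e-12)
  }
})

test_that("a single whole-trial window matches the direct fit", {
  rec <- tiny_preprocessed()
  x <- rec$sources[1:40, , 1:200]
  g <- segment(200, rec$fs, 1000 * 200 / rec$fs, 1000)
  expect_equal(g$n_windows, 1)
  ws <- ercnet:::causality_workspace(x, rep("a", 40), g, 2,
                                     c(10, 20), rec$fs)
  direct <- fit_var_multitrial(x, 2)
  viaws <- ercnet:::var_from_gram(
    rowSums(ercnet:::var_gram_trials(x, 2)), 6, 2, 40 * 198)
  expect_equal(direct$A, viaws$A, tolerance = 1e-12)
  map <- ercnet:::map_from_counts(ws, rep(1, 40))
  expect_equal(drop(map[, , 1, ]), ddtf(direct, c(10, 20), rec$fs)$ddtf,
               tolerance = 1e-10)
})
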