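# Tensor assembly bookkeeping and the constrained PARAFAC engine.

test_that("assembly reproduces the full-scale dimensionality instantly", {
  maps <- empty_delta_maps(c(49, 33, 36), n_windows = 160, n_bins = 19)
  t0 <- Sys.time()
  tens <- assemble_tensor(maps)
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  expect_equal(tens$dims, c(18, 3040, 4668))
  expect_equal(unname(tens$k_per_subject), c(49, 33, 36))
  expect_lt(elapsed, 1)
})

test_that("tiny assemblies and label round trips are exact", {
  maps <- empty_delta_maps(3, n_windows = 2, n_bins = 2)
  tens <- assemble_tensor(maps)
  expect_equal(tens$dims, c(18, 4, 6))
  expect_equal(dim(as.array(tens)), c(18, 4, 6))
  big <- assemble_tensor(empty_delta_maps(c(4, 3), 5, 3))
  set.seed(71)
  for (j in sample(big$dims[2], 50, replace = TRUE)) {
    lab <- ercnet:::tf_label(big, j)
    expect_equal(ercnet:::tf_index(big, lab$window, lab$bin), j)
  }
  for (l in sample(big$dims[3], 50, replace = TRUE)) {
    lab <- ercnet:::connection_label(big, l)
    expect_equal(ercnet:::connection_index(big, lab$subject, lab$source,
                                           lab$sink), l)
  }
})

test_that("entries land at their registry positions", {
  maps <- empty_delta_maps(3, n_windows = 2, n_bins = 2)
  d <- maps$S1[["ChRf-CmRf.Cplus"]]
  d <- tibble::add_row(d, sink = 2L, source = 3L, window = 2L, bin = 1L,
                       sign = -1L)
  attributes(d)[c("dims", "comparison", "n_cells", "alpha_fdr", "n_boot")] <-
    attributes(maps$S1[["ChRf-CmRf.Cplus"]])[c("dims", "comparison",
                                               "n_cells", "alpha_fdr",
                                               "n_boot")]
  class(d) <- class(maps$S1[["ChRf-CmRf.Cplus"]])
  maps$S1[["ChRf-CmRf.Cplus"]] <- d
  tens <- assemble_tensor(maps)
  arr <- as.array(tens)
  i <- which(tens$axes$comparison$comparison == "ChRf-CmRf.Cplus")
  j <- ercnet:::tf_index(tens, 2, 1)
  l <- ercnet:::connection_index(tens, "S1", 3, 2)
  expect_equal(arr[i, j, l], -1)
  expect_equal(sum(arr != 0), 1)
})

test_that("missing comparisons are reported by name", {
  maps <- empty_delta_maps(3, 2, 2)
  maps$S1[["CwRf-ChRf.Cminus"]] <- NULL
  err <- expect_error(assemble_tensor(maps), class = "ercnet_data_error")
  expect_match(conditionMessage(err), "CwRf-ChRf.Cminus")
})

test_that("an exact trilinear tensor is recovered to high congruence", {
  tri <- random_trilinear(c(10, 8, 12), 3, seed = 72)
  fit <- parafac(tri$x, 3, init = "random", n_init = 10, seed = 73)
  expect_gte(fit$fit, 99.9)
  for (mode in c("time_frequency", "connection")) {
    planted <- if (mode == "time_frequency") tri$B else tri$C
    cg <- abs(ercnet:::congruence(fit$loadings[[mode]], planted))
    perm <- ercnet:::match_columns(cg)
    expect_true(all(cg[cbind(seq_len(3), perm)] >= 0.99))
  }
  expect_gte(corcondia(fit, tri$x), 99)
})

test_that("constraints, determinism and fit monotonicity hold", {
  tri <- random_trilinear(c(8, 7, 9), 2, noise = 0.3, seed = 74)
  f1 <- parafac(tri$x, 1, init = "random", n_init = 5, seed = 75)
  expect_true(all(f1$loadings$time_frequency >= 0))
  expect_true(all(f1$loadings$connection >= 0))
  expect_equal(corcondia(f1, tri$x), 100) # single-component core is exact
  f1b <- parafac(tri$x, 1, init = "random", n_init = 5, seed = 75)
  expect_identical(f1b$loadings, f1$loadings)
  fits <- vapply(1:4, function(r) {
    parafac(tri$x, r, init = "random", n_init = 8, seed = 76)$fit
  }, 0)
  expect_true(all(diff(fits) > -0.5))
  expect_error(parafac(tri$x, 10), class = "ercnet_config_error")
})

test_that("unit-norm columns carry all scale in the comparison mode", {
  tri <- random_trilinear(c(6, 5, 7), 2, seed = 77)
  fit <- parafac(tri$x, 2, init = "dtld", seed = 78)
  expect_equal(colSums(fit$loadings$time_frequency^2), rep(1, 2),
               tolerance = 1e-8)
  expect_equal(colSums(fit$loadings$connection^2), rep(1, 2),
               tolerance = 1e-8)
})

test_that("over-factored noise tensors lose core consistency", {
  set.seed(79)
  cc <- replicate(10, {
    x <- array(rnorm(6 * 20 * 24), c(6, 20, 24))
    fit <- parafac(x, 4, init = "random", n_init = 5, screen_iter = 20,
                   max_iter = 300)
    corcondia(fit, x)
  })
  expect_lt(median(cc), 50)
})

test_that("the scan selects by the sharp-drop rule", {
  tri <- random_trilinear(c(12, 30, 40), 3, noise = 0.05, seed = 80)
  sc <- scan_components(tri$x, r_max = 5, n_init = 8, seed = 81)
  expect_equal(sc$selected_r, 3)
  expect_false(sc$flagged)
  expect_equal(nrow(sc$curve), 10) # both init methods at every r
  # degenerate threshold on an exact tensor: r_max itself is selected
  ex <- random_trilinear(c(8, 10, 12), 3, seed = 82)
  sc0 <- scan_components(ex$x, r_max = 3, threshold = 0, n_init = 4,
                         seed = 82)
  expect_equal(sc0$selected_r, 3)
  # pure noise: no sharp drop from a high plateau, flagged
  set.seed(83)
  noise <- array(rnorm(6 * 18 * 20), c(6, 18, 20))
  scn <- scan_components(noise, r_max = 4, n_init = 4, seed = 84)
  expect_true(scn$flagged || scn$selected_r == 1)
})

test_that("tidiers and plots summarize a fit", {
  tri <- random_trilinear(c(6, 5, 7), 2, seed = 85)
  fit <- parafac(tri$x, 2, init = "random", n_init = 4, seed = 86)
  td <- tidy(fit)
  expect_equal(nrow(td), (6 + 5 + 7) * 2)
  expect_setequal(unique(td$mode),
                  c("comparison", "time_frequency", "connection"))
  gl <- glance(fit)
  expect_equal(gl$r, 2)
  expect_s3_class(autoplot(fit), "ggplot")
})
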