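# Graphs from connection loadings, node strengths, channel projection,
# area flow, top-connection overlap, profiles and structure matching.

# a small fitted-model stand-in with axis registries
toy_model <- function(ks = c(3, 4), n_windows = 4, n_bins = 3, r = 2,
                      seed = 91) {
  set.seed(seed)
  tens <- assemble_tensor(empty_delta_maps(ks, n_windows, n_bins))
  m <- parafac(array(rnorm(prod(tens$dims), sd = 0.1) +
                       as.array(tens), tens$dims),
               r, init = "random", n_init = 3, seed = seed,
               max_iter = 50)
  m$axes <- tens$axes
  m$n_windows <- tens$n_windows
  list(model = m, tensor = tens)
}

test_that("mode-3 blocks split into per-subject graphs and back", {
  maps <- empty_delta_maps(c(49, 33, 36), 2, 2)
  tens <- assemble_tensor(maps)
  blocks <- as.integer(table(tens$axes$connection$subject)[c("S1", "S2", "S3")])
  expect_equal(blocks, c(2352L, 1056L, 1260L))
  toy <- toy_model()
  g <- loadings_to_graphs(toy$model)
  expect_equal(length(g), 2)
  expect_equal(dim(g[[1]]$S1), c(3, 3))
  expect_equal(dim(g[[1]]$S2), c(4, 4))
  expect_true(all(diag(g[[1]]$S1) == 0))
  # round trip: graph values equal the loading at the registry position
  ax <- toy$model$axes$connection
  C <- toy$model$loadings$connection
  for (l in sample(nrow(ax), 12)) {
    expect_equal(
      g[[1]][[ax$subject[l]]][ax$source[l], ax$sink[l]],
      C[l, 1]
    )
  }
})

test_that("node strengths obey the conservation identities", {
  g <- matrix(0, 3, 3); g[1, 2] <- 2.5
  ns <- node_strengths(g)
  expect_equal(ns$density[1:2], c(2.5, 2.5))
  expect_equal(ns$outflow[1:2], c(2.5, -2.5))
  expect_equal(ns$outflow[3], 0)
  expect_equal(sum(ns$outflow), 0)
  # uniform complete digraph
  k <- 4; w <- 0.7
  gu <- matrix(w, k, k); diag(gu) <- 0
  nu <- node_strengths(gu)
  expect_equal(nu$density, rep(2 * w * (k - 1), k))
  expect_equal(nu$outflow, rep(0, k))
  expect_true(all(nu$density >= abs(nu$outflow)))
  # random graph: conservation still exact
  set.seed(92)
  gr <- matrix(runif(25), 5, 5); diag(gr) <- 0
  expect_equal(sum(node_strengths(gr)$outflow), 0, tolerance = 1e-12)
})

test_that("channel projection is the peak-normalized weighted sum", {
  mix <- matrix(0, 4, 2)
  mix[2, 1] <- 1            # component 1 lives on channel 2
  mix[, 2] <- c(0.5, 1, -2, 0.2)
  vals <- c(3, 5)
  out <- project_to_channels(vals, mix)
  # oracle: direct summation
  oracle <- abs(mix[, 1]) / max(abs(mix[, 1])) * 3 +
    abs(mix[, 2]) / max(abs(mix[, 2])) * 5
  expect_equal(out, oracle)
  expect_equal(out[2], 3 + 5 * (1 / 2))
  # linearity
  expect_equal(project_to_channels(2 * vals, mix), 2 * out)
  expect_error(project_to_channels(vals, matrix(0, 4, 2)),
               class = "ercnet_data_error")
})

test_that("area max flow picks the strongest inter-area link", {
  g <- matrix(0, 4, 4)
  areas <- c("V", "V", "PF", "aT")
  g[1, 3] <- 2; g[2, 3] <- 5; g[1, 4] <- 1
  out <- area_max_flow(g, areas)
  expect_equal(out["V", "PF"], 5)
  expect_equal(out["V", "aT"], 1)
  expect_equal(out["PF", "V"], 0)
  expect_equal(sum(out), 6)
  expect_true(all(out <= max(g)))
  expect_setequal(attr(out, "empty_areas"), c("P", "mPF", "M", "pT"))
  expect_error(area_max_flow(g, rep("V", 4)), class = "ercnet_data_error")
})

test_that("top-connection overlap matches brute-force set intersection", {
  set.seed(93)
  g <- matrix(runif(100), 10, 10); diag(g) <- 0
  expect_equal(top_shared_connections(g, g, 0.1), 1.0)
  g2 <- matrix(0, 10, 10)
  g2[g < quantile(g[g > 0], 0.3)] <- runif(sum(g < quantile(g[g > 0], 0.3)))
  diag(g2) <- 0
  # disjoint supports at a tight quantile
  ga <- matrix(0, 6, 6); gb <- matrix(0, 6, 6)
  ga[1, 2] <- 1; ga[1, 3] <- 0.2
  gb[4, 5] <- 1; gb[4, 6] <- 0.2
  expect_equal(top_shared_connections(ga, gb, 0.4), 0)
  # constructed overlap verified against brute force
  gA <- matrix(0, 10, 10); gB <- matrix(0, 10, 10)
  offd <- which(row(gA) != col(gA))
  topA <- sample(offd, 10); shared <- sample(topA, 6)
  topB <- c(shared, sample(setdiff(offd, topA), 4))
  gA[topA] <- runif(10, 0.9, 1); gB[topB] <- runif(10, 0.9, 1)
  rest <- sample(setdiff(offd, union(topA, topB)), 30)
  gA[rest] <- runif(30, 0.01, 0.1); gB[rest] <- runif(30, 0.01, 0.1)
  q <- 10 / 40
  ratio <- top_shared_connections(gA, gB, q)
  maskA <- ercnet:::top_connection_mask(gA, q)
  maskB <- ercnet:::top_connection_mask(gB, q)
  expect_equal(ratio, sum(maskA & maskB) / sum(maskA))
  expect_equal(ratio, 0.6)
  expect_error(top_shared_connections(matrix(0, 3, 3), ga[1:3, 1:3], 0.1),
               class = "ercnet_data_error")
})

test_that("undirected pathways ignore direction and track sharing", {
  g1 <- matrix(0, 4, 4); g2 <- matrix(0, 4, 4)
  g1[1, 2] <- 1; g1[3, 4] <- 0.9; g1[1, 3] <- 0.05
  g2[2, 1] <- 1; g2[3, 4] <- 0.9; g2[2, 4] <- 0.05
  out <- undirected_pathways(list(g1, g2), q = 0.67)
  both <- out[out$shared_all, ]
  expect_setequal(paste(both$node_a, both$node_b), c("1 2", "3 4"))
  # identical graphs: intersection equals union
  out2 <- undirected_pathways(list(g1, g1), q = 0.67)
  expect_true(all(out2$shared_all))
})

test_that("profiles are the stated sums and means over the TF grid", {
  toy <- toy_model(ks = 3, n_windows = 5, n_bins = 4)
  pr <- profiles(toy$model)
  expect_equal(dim(pr$temporal), c(5, 2))
  expect_equal(dim(pr$spectral), c(4, 2))
  expect_true(all(pr$temporal >= 0) && all(pr$spectral >= 0))
  # separable planted column: profiles proportional to its factors
  u <- runif(5); v <- runif(4)
  toy$model$loadings$time_frequency[, 1] <- as.vector(outer(u, v))
  pr2 <- profiles(toy$model)
  expect_gt(cor(pr2$temporal[, 1], u * sum(v)), 0.999999)
  expect_gt(cor(pr2$spectral[, 1], v), 0.999999)
  # at the full-scale grid the lengths match the published design
  maps <- empty_delta_maps(c(49, 33, 36), 160, 19)
  tens <- assemble_tensor(maps)
  expect_equal(max(tens$axes$time_frequency$window), 160)
  expect_equal(max(tens$axes$time_frequency$bin), 19)
})

test_that("structure matching recovers permutations and itself", {
  toy <- toy_model(ks = c(4, 3), n_windows = 6, n_bins = 4, r = 3,
                   seed = 94)
  m <- toy$model
  self <- compare_structures(m, m)
  expect_equal(self$assignment, 1:3)
  expect_equal(self$matched$rho[self$matched$domain == "comparison"],
               rep(1, 3), tolerance = 1e-12)
  # permuted copy: permutation recovered exactly
  perm <- c(3, 1, 2)
  m2 <- m
  for (mode in names(m$loadings)) {
    m2$loadings[[mode]] <- m$loadings[[mode]][, perm]
  }
  out <- compare_structures(m, m2)
  expect_equal(out$assignment, order(perm))
  # outflow vectors concatenate across subjects (full-scale length 118)
  maps <- empty_delta_maps(c(49, 33, 36), 2, 2)
  tens <- assemble_tensor(maps)
  g1 <- loadings_to_graphs(list(r = 1,
                                loadings = list(connection =
                                  matrix(1, tens$dims[3], 1))),
                           axes = tens$axes)
  of <- unlist(lapply(g1[[1]], function(g) node_strengths(g)$outflow))
  expect_equal(length(of), 118)
})
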