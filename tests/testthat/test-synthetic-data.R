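test_that("ground-truth construction is deterministic and positive definite", {
  t1 <- make_true_network(seed = 9)
  t2 <- make_true_network(seed = 9)
  expect_identical(t1$partial, t2$partial)
  expect_gt(min(eigen(t1$precision, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
  # within-cluster weights drawn inside the requested band
  emo <- c("irritable", "depressed", "frustrated")
  w <- t1$partial[emo, emo][upper.tri(diag(3))]
  expect_true(all(w >= 0.29 & w <= 0.46))
  # upper bound of the band remains feasible
  hi <- make_true_network(seed = 1,
                          cluster_weight_range = c(0.46, 0.46))
  expect_gt(min(eigen(hi$precision, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
})

test_that("degenerate edge configurations behave as designed", {
  # no cross-cluster edges: block-diagonal partial structure
  blk <- make_true_network(seed = 2, cross_edges = NULL)
  P <- blk$partial
  emo <- c("irritable", "depressed", "frustrated")
  outside <- setdiff(rpq_items(), emo)
  expect_true(all(P[emo, outside] == 0))
  # all edges zero: full independence
  none <- make_true_network(seed = 2, cluster_weight_range = c(0, 0),
                            cross_edges = NULL)
  expect_true(all(none$partial[upper.tri(none$partial)] == 0))
  expect_equal(unname(none$sigma), diag(16))
})

test_that("the designed top node is the cognitive composite", {
  tr <- make_true_network(seed = 4)
  expect_identical(tr$designed_top, "cognitive")
  expect_gt(tr$node_ei["cognitive"], max(tr$node_ei[
    setdiff(names(tr$node_ei), "cognitive")]))
})

test_that("cohorts are reproducible, ordinal and complete", {
  tr <- make_true_network(seed = 5)
  c1 <- simulate_cohort(tr, 100, seed = 11)
  c2 <- simulate_cohort(tr, 100, seed = 11)
  attr(c1, "truth") <- attr(c2, "truth") <- NULL
  expect_identical(c1, c2)
  c3 <- simulate_cohort(tr, 100, seed = 12)
  expect_false(identical(c1[, rpq_items()], c3[, rpq_items()]))
  expect_true(all(as.matrix(c1[, rpq_items()]) %in% 0:4))
  expect_equal(nrow(c1), 100 * 4)
  expect_true(all(is.na(c1$gose[c1$timepoint == "W2"])))
  expect_true(all(c1$gose[c1$timepoint == "M12"] %in% 7:8))
})

test_that("marginal category frequencies match the copula closed form", {
  tr <- make_true_network(seed = 6)
  n <- 10000
  co <- simulate_cohort(tr, n, timepoints = "W2", seed = 13)
  for (it in c("headache", "nausea", "fatigue")) {
    tau <- tr$thresholds[it, ]
    probs <- diff(c(0, pnorm(tau), 1))
    obs <- tabulate(co[[it]] + 1L, 5) / n
    se <- sqrt(probs * (1 - probs) / n)
    expect_true(all(abs(obs - probs) <= 3 * se + 1e-9),
                info = it)
  }
})

test_that("latent partial correlations are recovered from large samples", {
  tr <- make_true_network(seed = 7)
  set.seed(77)
  z <- mvn_sample(tr$sigma, 5000)
  P_hat <- precision_to_partial(solve(cor(z)))
  emo <- match(c("irritable", "depressed", "frustrated"), tr$items)
  expect_lt(max(abs(P_hat[emo, emo] - tr$partial[emo, emo])), 0.05)
})

test_that("null pairs share the generating network and differ by seed", {
  tr <- make_true_network(seed = 8)
  pr <- null_pair(tr, 120, seed = 21, paired = TRUE)
  expect_identical(rownames(pr$A), rownames(pr$B))
  expect_identical(colnames(pr$A), network_nodes())
  p1 <- null_pair(tr, 120, seed = 22)
  p2 <- null_pair(tr, 120, seed = 23)
  expect_false(identical(p1$A, p2$A))
})
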