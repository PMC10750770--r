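test_that("correlation estimation validates input and flags degeneracy", {
  set.seed(11)
  x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  dup <- cbind(x, d = x[, "a"])
  expect_warning(S <- node_correlation(dup), "collinear")
  expect_equal(S["a", "d"], 1)
  neg <- cbind(x, d = -x[, "a"])
  expect_equal(suppressWarnings(node_correlation(neg))["a", "d"], -1)
  flat <- cbind(x, d = 1)
  expect_error(node_correlation(flat), "zero-variance node\\(s\\): d")
  expect_error(node_correlation(x[1:3, ]), "complete rows")
})

test_that("independent columns give near-zero correlations at large n", {
  set.seed(12)
  n <- 10000
  x <- matrix(rnorm(n * 5), n, 5)
  S <- node_correlation(x)
  expect_lt(max(abs(S[upper.tri(S)])), 3 / sqrt(n))
  expect_equal(max(abs(S - t(S))), 0)
  expect_equal(unname(diag(S)), rep(1, 5))
})

test_that("full shrinkage yields the empty graph and zero penalty the MLE", {
  S <- rand_cor(5, seed = 21)
  lmax <- max(abs(S[upper.tri(S)]))
  Th <- graphical_lasso(S, lmax + 1e-12)
  expect_true(all(Th[upper.tri(Th)] == 0))
  expect_equal(unname(diag(Th)), 1 / diag(S))
  T0 <- graphical_lasso(S, 0)
  expect_lt(max(abs(T0 - solve(S))), 1e-6)
})

test_that("glasso matches an independent ADMM solve of the same objective", {
  for (seed in c(31, 32)) {
    for (p in 3:4) {
      S <- rand_cor(p, seed = seed)
      for (lam in c(0.02, 0.1, 0.3)) {
        mine <- graphical_lasso(S, lam, tol = 1e-9)
        oracle <- admm_glasso(S, lam)
        expect_lt(max(abs(mine - oracle)), 1e-5)
      }
    }
  }
})

test_that("the spec'd 3-node covariance solves to the oracle solution", {
  S <- matrix(c(1, 0.5, 0.3,
                0.5, 1, 0.2,
                0.3, 0.2, 1), 3, 3)
  mine <- graphical_lasso(S, 0.1, tol = 1e-9)
  oracle <- admm_glasso(S, 0.1)
  expect_lt(max(abs(mine - oracle)), 1e-5)
})

test_that("EBIC follows its closed form and penalizes density", {
  S <- rand_cor(4, seed = 41)
  Th <- graphical_lasso(S, 0.05)
  n <- 200
  E <- sum(Th[upper.tri(Th)] != 0)
  ll <- (n / 2) * (determinant(Th)$modulus[1] - sum(S * Th))
  expect_equal(ebic(Th, S, n, gamma = 0), -2 * ll + E * log(n))
  expect_equal(ebic(Th, S, n, gamma = 0.5),
               -2 * ll + E * log(n) + 4 * E * 0.5 * log(4))
  # denser model with identical likelihood scores worse for gamma > 0
  Th_dense <- graphical_lasso(S, 0)
  E2 <- sum(Th_dense[upper.tri(Th_dense)] != 0)
  expect_gt(E2, E)
  expect_gt(ebic(Th_dense, S, n, 0.5) - ebic(Th_dense, S, n, 0),
            ebic(Th, S, n, 0.5) - ebic(Th, S, n, 0))
  # hand-computed 2-node penalty: E = 1, n = 100, p = 2
  S2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  Th2 <- graphical_lasso(S2, 0.01)
  pen <- ebic(Th2, S2, 100, 0.5) - ebic(Th2, S2, 100, 0)
  expect_equal(pen, 2 * log(2))   # 4 * E * gamma * log(p), E = 1
})

test_that("precision-to-partial transform has the expected structure", {
  S <- rand_cor(6, seed = 51)
  Th <- graphical_lasso(S, 0.05)
  W <- precision_to_partial(Th)
  expect_equal(unname(diag(W)), rep(0, 6))
  expect_equal(W, t(W))
  off <- upper.tri(W)
  expect_true(all(sign(W[off]) == -sign(Th[off])))
  expect_true(all(abs(W[off]) < 1))
  expect_equal(precision_to_partial(diag(6)), matrix(0, 6, 6))
})

test_that("EBIC selection returns a coherent network object", {
  set.seed(61)
  Sigma <- partial_to_covariance(chain_partial(10, 0.3))
  x <- mvn_sample(Sigma, 800)
  colnames(x) <- colnames(Sigma)
  net <- select_network(x)
  expect_s3_class(net, "ggm_network")
  expect_equal(net$n, 800)
  expect_equal(net$gamma, 0.5)
  # weight/precision supports coincide
  expect_identical(support_of(net$W), support_of(net$Theta))
  # edge count is non-increasing in lambda (path stored decreasing)
  expect_true(all(diff(net$edge_path) >= 0))
  # selected EBIC is the path minimum, ties to sparser (earlier) lambda
  expect_equal(net$ebic, min(net$ebic_path))
  expect_gte(net$lambda, net$lambda_path[which.min(net$ebic_path)])
})

test_that("independence data select the empty or near-empty graph", {
  set.seed(71)
  x <- matrix(rnorm(500 * 8), 500, 8,
              dimnames = list(NULL, paste0("V", 1:8)))
  net <- select_network(x)
  expect_lte(net$edge_count, 1)
})

test_that("network JSON round-trips bit-stably and edge list is tidy", {
  set.seed(81)
  Sigma <- partial_to_covariance(chain_partial(6, 0.35))
  x <- mvn_sample(Sigma, 400)
  colnames(x) <- colnames(Sigma)
  net <- select_network(x)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_network_json(net, f1)
  back <- read_network_json(f1)
  expect_equal(back$W, net$W)
  expect_equal(back$lambda, net$lambda)
  write_network_json(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  el <- network_edgelist(net)
  expect_named(el, c("node_i", "node_j", "weight"))
  expect_equal(nrow(el), net$edge_count)
})
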