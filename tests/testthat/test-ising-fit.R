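test_that("the lambda-max end of the path shrinks everything to zero", {
  X <- sample_ising_exact(toy_pair_model(), rep(-0.5, 4), 800, seed = 61)
  path <- fit_nodewise_lasso(X, 1)
  expect_equal(path$df[1], 0)
  expect_true(all(path$beta[, 1] == 0))
  # intercept-only log-likelihood in closed form
  ybar <- mean(X[, 1])
  ll0 <- nrow(X) * (ybar * log(ybar) + (1 - ybar) * log(1 - ybar))
  expect_equal(path$loglik[1], ll0, tolerance = 1e-6)
  expect_equal(path$ebic[1], -2 * ll0, tolerance = 1e-6)
})

test_that("EBIC values and selection are reproducible from the path components", {
  X <- sample_ising_exact(toy_pair_model(), rep(-0.5, 4), 800, seed = 62)
  path <- fit_nodewise_lasso(X, 2, gamma = 0.25)
  manual <- -2 * path$loglik + path$df * log(path$n) +
    2 * 0.25 * path$df * log(length(path$predictors))
  expect_equal(path$ebic, manual)
  expect_equal(path$selected, which.min(manual))
  # non-zero count is monotone non-increasing in lambda
  expect_true(all(diff(path$df[order(path$lambda)]) <= 0))
})

test_that("KKT optimality holds along the solution path", {
  X <- sample_ising_exact(toy_pair_model(), rep(-0.5, 4), 1500, seed = 63)
  for (node in 1:4) {
    path <- fit_nodewise_lasso(X, node)
    for (l in seq(1, length(path$lambda), by = 7)) {
      b <- path$beta[, l]
      g <- path$grad[, l]
      lam <- path$lambda[l]
      expect_true(all(abs(g[b == 0]) <= lam + 1e-5))
      if (any(b != 0)) {
        expect_lt(max(abs(g[b != 0] + lam * sign(b[b != 0]))), 1e-5)
      }
    }
  }
})

test_that("penalised path solutions agree with glmnet on a shared grid", {
  skip_if_not_installed("glmnet")
  X <- sample_ising_exact(toy_pair_model(), c(-0.5, 0.2, -1, 0.4), 1200,
                          seed = 64)
  path <- fit_nodewise_lasso(X, 1)
  lam_pick <- path$lambda[c(20, 45, 80)]
  gfit <- glmnet::glmnet(X[, -1], X[, 1], family = "binomial",
                         lambda = path$lambda, standardize = FALSE,
                         thresh = 1e-12)
  for (l in c(20, 45, 80)) {
    expect_equal(as.numeric(gfit$beta[, l]), path$beta[, l],
                 tolerance = 1e-4)
  }
})

test_that("EBIC-selected support matches the exhaustive all-subsets oracle", {
  # p = 4 with one strong planted pair: nodewise selection, the exhaustive
  # ML + EBIC search, and the planted neighbour set should coincide
  # (occasional disagreement from lasso shrinkage is a ~5% event; the rate
  # itself is asserted in the acceptance suite)
  W <- fixture_matrix(paste0("v", 1:4), list(list("v1", "v2", 1.5)))
  X <- sample_ising_exact(W, rep(-0.5, 4), 2000, seed = 66)
  for (node in 1:4) {
    path <- fit_nodewise_lasso(X, node)
    support <- names(which(selected_coefs(path) != 0))
    oracle <- ebic_exhaustive_oracle(X, node)
    expect_setequal(support, oracle$support)
  }
  expect_setequal(names(which(selected_coefs(fit_nodewise_lasso(X, 1)) != 0)),
                  "v2")
  expect_setequal(names(which(selected_coefs(fit_nodewise_lasso(X, 3)) != 0)),
                  character(0))
})

test_that("symmetrisation follows the AND/OR rules with weight averaging", {
  mkpath <- function(node, preds, coefs, intercept = -1) {
    beta <- matrix(coefs, ncol = 1)
    structure(list(node = node, predictors = preds, lambda = 0.1,
                   beta = beta, intercept = intercept, loglik = -10,
                   df = sum(coefs != 0), ebic = 20, grad = beta * 0,
                   selected = 1L, gamma = 0.25, n = 100),
              class = "ebic_path")
  }
  paths <- list(mkpath("a", c("b", "c"), c(0.6, 0.8)),
                mkpath("b", c("a", "c"), c(0.4, 0.0)),
                mkpath("c", c("a", "b"), c(0.0, 0.0)))
  net_and <- assemble_network(paths, rule = "AND")
  expect_equal(net_and$weights["a", "b"], 0.5)   # mean(0.6, 0.4)
  expect_equal(net_and$weights["a", "c"], 0)     # one direction missing
  net_or <- assemble_network(paths, rule = "OR")
  expect_equal(net_or$weights["a", "c"], 0.4)    # mean(0.8, 0)
  expect_equal(net_or$weights["b", "c"], 0)
  expect_true(isSymmetric(net_and$weights))
  expect_equal(unname(net_and$thresholds), rep(-1, 3))
})

test_that("independent data rarely produce false edges", {
  # EBIC-lasso is conservative under the null: per-pair false edge rate
  # should stay below 5% across replicates
  W0 <- fixture_matrix(paste0("v", 1:5), list())
  false_edges <- vapply(1:12, function(r) {
    X <- sample_ising_exact(W0, rep(-0.3, 5), 1500, seed = 70 + r)
    net <- estimate_ising_network(X)
    sum(net$weights[upper.tri(net$weights)] != 0)
  }, 0)
  expect_lt(mean(false_edges) / 10, 0.05)
})

test_that("constant nodes are dropped and recorded; small strata are skipped", {
  X <- sample_ising_exact(toy_pair_model(), rep(-0.5, 4), 500, seed = 81)
  X <- cbind(X, dead = 0L)
  net <- estimate_ising_network(X)
  expect_named(net$dropped_nodes, "dead")
  expect_false("dead" %in% net$nodes)
  cc <- classify_mm(fit_ipw_weights(quick_cohort(900, seed = 83)))
  ws <- capture_warnings(nets <- estimate_stratified_networks(cc, min_n = 500))
  expect_true(any(grepl("skipped", ws)))
  expect_true(length(nets) < 5)
  for (net in nets) expect_true(isSymmetric(net$weights))
})

test_that("network estimation is deterministic for identical data", {
  X <- sample_ising_exact(toy_pair_model(), rep(-0.5, 4), 700, seed = 85)
  expect_identical(estimate_ising_network(X), estimate_ising_network(X))
})
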