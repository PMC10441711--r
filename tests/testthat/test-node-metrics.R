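test_that("an isolated node's predictability equals its base rate", {
  W <- fixture_matrix(c("x", "y", "z"),
                      list(list("y", "z", 1.2)))  # x isolated
  net <- fixture_network(W)
  set.seed(111)
  n <- 500
  X <- cbind(x = rbinom(n, 1, 0.7), y = rbinom(n, 1, 0.5),
             z = rbinom(n, 1, 0.5))
  phat <- mean(X[, "x"])
  # an isolated node's fitted threshold is the intercept-only logit, so the
  # model predicts the majority class and CC collapses to the base rate
  net$thresholds["x"] <- qlogis(phat)
  row <- predictability_cc(X, net)[1, ]
  expect_equal(row$cc_baseline, max(phat, 1 - phat))
  expect_equal(row$cc, max(phat, 1 - phat), tolerance = 1 / n)
  # and the estimator reproduces that when x really is independent
  net2 <- estimate_ising_network(X)
  if (sum(net2$weights["x", ]) == 0) {
    r2 <- predictability_cc(X, net2)
    expect_equal(r2$cc[r2$node == "x"], r2$cc_baseline[r2$node == "x"],
                 tolerance = 1 / n)
  }
})

test_that("a deterministically coupled pair approaches perfect predictability", {
  W <- fixture_matrix(c("a", "b"), list(list("a", "b", 12)))
  net <- fixture_network(W)
  net$thresholds[] <- c(-6, -6)  # P(a=1|b=1) ~ logistic(6)
  X <- sample_ising_exact(W, net$thresholds, 4000, seed = 113)
  cc <- predictability_cc(X, net)
  expect_gt(min(cc$cc), 0.98)
  expect_gt(mean(X[, "a"] == X[, "b"]), 0.98)
})

test_that("in-sample CC dominates the baseline up to thresholding noise", {
  W <- toy_pair_model()
  X <- sample_ising_exact(W, rep(-0.5, 4), 2500, seed = 115)
  net <- estimate_ising_network(X)
  tab <- predictability_cc(X, net)
  expect_true(all(tab$cc >= tab$cc_baseline - 0.02))
})

test_that("path-graph centralities match hand enumeration", {
  W <- path_fixture()
  net <- fixture_network(W)
  cent <- centralities(net)
  expect_equal(cent$betweenness, c(0, 1, 0))
  expect_equal(cent$closeness[2], 1)        # 2 reachable / total distance 2
  expect_equal(cent$closeness[1], 2 / 3)    # distances 1 and 2
  expect_equal(cent$strength, c(1, 2, 1))
})

test_that("centralities agree with brute-force oracles on random small graphs", {
  set.seed(117)
  for (rep in 1:6) {
    n <- sample(4:8, 1)
    W <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < 0.5) {
        w <- round(runif(1, 0.2, 2), 2) * sample(c(-1, 1), 1)
        W[i, j] <- W[j, i] <- w
      }
    }
    net <- fixture_network(W)
    cent <- centralities(net)
    expect_equal(cent$strength, rowSums(abs(W)), ignore_attr = TRUE,
                 tolerance = 1e-9)
    expect_equal(cent$closeness, closeness_oracle(W), tolerance = 1e-9)
    expect_equal(cent$betweenness, betweenness_oracle(W), tolerance = 1e-9)
    memb <- stats::setNames(sample(1:2, n, replace = TRUE), letters[1:n])
    centp <- centralities(net, memb)
    expect_equal(centp$participation, participation_oracle(W, memb),
                 tolerance = 1e-9)
  }
})

test_that("participation coefficient follows its closed form", {
  # half the strength in each of two communities -> P = 0.5
  W <- fixture_matrix(c("hub", "in1", "out1"),
                      list(list("hub", "in1", 1), list("hub", "out1", 1)))
  net <- fixture_network(W)
  memb <- c(hub = 1L, in1 = 1L, out1 = 2L)
  cent <- centralities(net, memb)
  expect_equal(cent$participation[cent$node == "hub"], 0.5)
  # all edges within the own community -> P = 0
  memb1 <- c(hub = 1L, in1 = 1L, out1 = 1L)
  cent1 <- centralities(net, memb1)
  expect_equal(cent1$participation, rep(0, 3))
  # relabelling communities leaves P unchanged
  memb2 <- c(hub = 9L, in1 = 9L, out1 = 4L)
  expect_equal(centralities(net, memb2)$participation, cent$participation)
})

test_that("held-out CC evaluation and centrality z-scores behave", {
  W <- toy_pair_model()
  X <- sample_ising_exact(W, rep(-0.5, 4), 1500, seed = 119)
  Xnew <- sample_ising_exact(W, rep(-0.5, 4), 1500, seed = 120)
  net <- estimate_ising_network(X)
  oos <- predictability_cc(X, net, newdata = Xnew)
  expect_true(all(oos$cc >= 0 & oos$cc <= 1))
  # out-of-sample CC stays close to (and cannot systematically beat)
  # the in-sample value on iid draws from the same model
  ins <- predictability_cc(X, net)
  expect_lt(max(abs(oos$cc - ins$cc)), 0.05)
  z <- centrality_zscores(centralities(net))
  expect_equal(mean(z$strength), 0, tolerance = 1e-12)
  expect_equal(sd(z$strength), 1, tolerance = 1e-12)
  zc <- centrality_zscores(data.frame(node = c("a", "b"),
                                      strength = c(1, 1),
                                      betweenness = c(0, 2)))
  expect_equal(zc$strength, c(0, 0))
})

test_that("strength equals degree on unit-weight graphs and isolates are zero", {
  W <- two_clique_fixture()
  cent <- centralities(fixture_network(W))
  expect_equal(cent$strength, rowSums(W != 0), ignore_attr = TRUE)
  Wi <- fixture_matrix(c("a", "b", "iso"), list(list("a", "b", 1)))
  ci <- centralities(fixture_network(Wi))
  row <- ci[ci$node == "iso", ]
  expect_equal(unlist(row[, c("strength", "closeness", "betweenness")]),
               c(strength = 0, closeness = 0, betweenness = 0))
})
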