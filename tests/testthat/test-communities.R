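test_that("walktrap recovers the two-clique partition and the exact optimum Q", {
  W <- two_clique_fixture()
  net <- fixture_network(W)
  part <- walktrap_communities(net, steps = 4)
  oracle <- best_partition_oracle(W)
  expect_true(same_partition(part$membership, oracle$membership))
  expect_equal(part$modularity, oracle$modularity, tolerance = 1e-9)
  expect_equal(part$modularity, 5 / 14, tolerance = 1e-9)  # = 0.3571...
})

test_that("walktrap modularity matches the exhaustive optimum on random graphs", {
  # walktrap is hierarchical so it cannot always reach the global optimum,
  # but on these small, well-separated fixtures it should
  set.seed(91)
  for (rep in 1:5) {
    n <- sample(5:7, 1)
    W <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    # two planted blocks with dense inside, single link between
    cut <- sample(2:(n - 2), 1)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      same <- (i <= cut) == (j <= cut)
      if (same) W[i, j] <- W[j, i] <- 1
    }
    W[cut, cut + 1] <- W[cut + 1, cut] <- 0.5
    part <- walktrap_communities(fixture_network(W))
    oracle <- best_partition_oracle(W)
    expect_equal(part$modularity, oracle$modularity, tolerance = 1e-9)
  }
})

test_that("degenerate graphs fall back to singletons and components stay apart", {
  empty <- fixture_network(fixture_matrix(letters[1:4], list()))
  part <- walktrap_communities(empty)
  expect_equal(length(unique(part$membership)), 4)
  expect_equal(part$modularity, 0)
  # disconnected components can never share a community
  W <- fixture_matrix(letters[1:6], list(
    list("a", "b", 1), list("b", "c", 1),
    list("d", "e", 1), list("e", "f", 1)))
  part2 <- walktrap_communities(fixture_network(W))
  left <- part2$membership[c("a", "b", "c")]
  right <- part2$membership[c("d", "e", "f")]
  expect_length(intersect(left, right), 0)
  # negative edges are used through their magnitude
  Wn <- W
  Wn["a", "b"] <- Wn["b", "a"] <- -1
  part3 <- walktrap_communities(fixture_network(Wn))
  expect_equal(length(unique(part3$membership)),
               length(unique(part2$membership)))
})

test_that("node relabelling permutes membership identically", {
  W <- two_clique_fixture()
  perm <- c(4, 1, 6, 2, 5, 3)
  Wp <- W[perm, perm]
  p1 <- walktrap_communities(fixture_network(W))
  p2 <- walktrap_communities(fixture_network(Wp))
  expect_true(same_partition(p1$membership[rownames(Wp)], p2$membership))
})

test_that("partition alignment is exact on permuted labels and self-identity", {
  ref <- c(a = 1L, b = 1L, c = 2L, d = 2L, e = 3L)
  expect_identical(mmnet:::align_partition(ref, ref), ref)
  relab <- c(a = 7L, b = 7L, c = 5L, d = 5L, e = 9L)
  expect_identical(mmnet:::align_partition(ref, relab), ref)
  # splitting one reference community: the larger piece keeps the label,
  # the smaller piece gets a fresh label beyond the reference's range
  ref2 <- c(a = 1L, b = 1L, c = 2L, d = 2L, e = 3L, f = 3L, g = 3L)
  split <- c(a = 9L, b = 9L, c = 8L, d = 8L, e = 7L, f = 7L, g = 5L)
  ali <- mmnet:::align_partition(ref2, split)
  expect_identical(ali[c("a", "b", "c", "d", "e", "f")],
                   ref2[c("a", "b", "c", "d", "e", "f")])
  expect_gt(ali[["g"]], 3L)
})

test_that("community naming is automatic, overridable, and label-invariant", {
  part <- structure(list(membership = c(parkinsons = 1L, alzheimers = 1L,
                                        copd = 2L, asthma = 2L),
                         modularity = 0.4, steps = 4, method = "walktrap"),
                    class = "community_partition")
  nm <- name_communities(part)
  expect_equal(unname(nm[["1"]]), "alzheimers–parkinsons")
  over <- name_communities(part, naming = c(`2` = "respiratory"))
  expect_equal(unname(over[["2"]]), "respiratory")
  # relabelling communities yields the same set of names
  part2 <- part
  part2$membership <- c(parkinsons = 2L, alzheimers = 2L,
                        copd = 1L, asthma = 1L)
  expect_setequal(unname(name_communities(part2)), unname(nm))
})

test_that("bootstrap stability separates strong block structure from noise", {
  # strong two-block model: high within-block couplings, none between
  nodes <- paste0("v", 1:6)
  W <- fixture_matrix(nodes, list(
    list("v1", "v2", 1.5), list("v1", "v3", 1.5), list("v2", "v3", 1.5),
    list("v4", "v5", 1.5), list("v4", "v6", 1.5), list("v5", "v6", 1.5)))
  X <- sample_ising_exact(W, rep(-0.8, 6), 1200, seed = 101)
  stab <- community_bootstrap(X, n_boot = 25, seed = 102)
  expect_true(stab$stable)
  expect_gt(mean(stab$agreement, na.rm = TRUE), 0.9)
  expect_equal(dim(stab$membership), c(25L, 6L))
  # independent noise: no community signal, flagged unstable
  W0 <- fixture_matrix(nodes, list())
  X0 <- sample_ising_exact(W0, rep(-0.8, 6), 600, seed = 103)
  stab0 <- community_bootstrap(X0, n_boot = 15, seed = 104)
  expect_false(stab0$stable)
  # degenerate budget
  expect_error(community_bootstrap(X, n_boot = 0), "n_boot")
})

test_that("bootstrap stability runs are seed-reproducible", {
  nodes <- paste0("v", 1:4)
  W <- fixture_matrix(nodes, list(list("v1", "v2", 1.4),
                                  list("v3", "v4", 1.4)))
  X <- sample_ising_exact(W, rep(-0.5, 4), 700, seed = 105)
  s1 <- community_bootstrap(X, n_boot = 10, seed = 106)
  s2 <- community_bootstrap(X, n_boot = 10, seed = 106)
  expect_identical(s1$membership, s2$membership)
  expect_identical(s1$consensus, s2$consensus)
})
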