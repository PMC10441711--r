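# Independent brute-force oracles and small fixtures used across the suite.
# These deliberately avoid the package's own code paths (and igraph where
# the package itself uses igraph), so agreement is a genuine cross-check.

# ---- fixtures ---------------------------------------------------------------

# symmetric weight matrix from an edge list (i, j, w)
fixture_matrix <- function(nodes, edges) {
  W <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (e in edges) W[e[[1]], e[[2]]] <- W[e[[2]], e[[1]]] <- e[[3]]
  W
}

# wrap a weight matrix as an ising_network (thresholds zero)
fixture_network <- function(W, n = 100) {
  structure(list(nodes = rownames(W), weights = W,
                 thresholds = stats::setNames(rep(0, nrow(W)), rownames(W)),
                 gamma = 0.25, n = n, rule = "AND",
                 dropped_nodes = character(0)),
            class = "ising_network")
}

# two 3-cliques joined by a single bridge edge, unit weights
two_clique_fixture <- function() {
  nodes <- letters[1:6]
  fixture_matrix(nodes, list(
    list("a", "b", 1), list("a", "c", 1), list("b", "c", 1),
    list("d", "e", 1), list("d", "f", 1), list("e", "f", 1),
    list("c", "d", 1)))
}

path_fixture <- function() {
  fixture_matrix(c("a", "b", "c"),
                 list(list("a", "b", 1), list("b", "c", 1)))
}

# ---- set partitions and modularity -----------------------------------------

# all set partitions of seq_len(n) (restricted growth strings)
all_partitions <- function(n) {
  parts <- list()
  rec <- function(labels, maxlab) {
    k <- length(labels)
    if (k == n) {
      parts[[length(parts) + 1]] <<- labels
      return(invisible(NULL))
    }
    for (lab in seq_len(maxlab + 1)) {
      rec(c(labels, lab), max(maxlab, lab))
    }
  }
  rec(integer(0), 0L)
  parts
}

# weighted Newman modularity of a membership vector on weight matrix A >= 0
modularity_oracle <- function(A, membership) {
  m2 <- sum(A)
  if (m2 == 0) return(0)
  k <- rowSums(A)
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    q <- q + sum(A[idx, idx]) / m2 - (sum(k[idx]) / m2)^2
  }
  q
}

# exhaustive modularity maximisation over all partitions (n <= 8)
best_partition_oracle <- function(A) {
  n <- nrow(A)
  best_q <- -Inf
  best <- NULL
  for (p in all_partitions(n)) {
    q <- modularity_oracle(A, p)
    if (q > best_q + 1e-12) {
      best_q <- q
      best <- p
    }
  }
  list(membership = best, modularity = best_q)
}

same_partition <- function(a, b) {
  # label-invariant comparison
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# ---- shortest paths, closeness, betweenness --------------------------------

# Floyd-Warshall all-pairs distances with lengths 1/|w|
floyd_distances <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  len <- ifelse(W != 0, 1 / abs(W), Inf)
  D <- pmin(D, len)
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

closeness_oracle <- function(W) {
  D <- floyd_distances(W)
  vapply(seq_len(nrow(W)), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (!length(d)) return(0)
    length(d) / sum(d)
  }, 0)
}

# geodesic counts by recursive enumeration of all shortest paths
betweenness_oracle <- function(W) {
  n <- nrow(W)
  D <- floyd_distances(W)
  len <- ifelse(W != 0, 1 / abs(W), Inf)
  # enumerate all shortest s->t paths as node sequences
  paths_between <- function(s, t) {
    if (s == t) return(list(s))
    if (!is.finite(D[s, t])) return(list())
    out <- list()
    for (v in seq_len(n)) {
      if (v != s && is.finite(len[s, v]) &&
          abs(len[s, v] + D[v, t] - D[s, t]) < 1e-9) {
        for (p in paths_between(v, t)) out[[length(out) + 1]] <- c(s, p)
      }
    }
    out
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq((s + 1), n)) {
      ps <- paths_between(s, t)
      if (!length(ps)) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        inner <- sum(vapply(ps, function(p) v %in% p, logical(1)))
        btw[v] <- btw[v] + inner / length(ps)
      }
    }
  }
  btw
}

participation_oracle <- function(W, membership) {
  A <- abs(W)
  vapply(seq_len(nrow(A)), function(i) {
    k <- sum(A[i, ])
    if (k == 0) return(0)
    1 - sum(tapply(A[i, ], membership, sum)^2) / k^2
  }, 0)
}

# ---- exhaustive nodewise EBIC search ---------------------------------------

# maximum-likelihood logistic fit + EBIC for every predictor subset
ebic_exhaustive_oracle <- function(X, node, gamma = 0.25) {
  y <- X[, node]
  Z <- X[, -node, drop = FALSE]
  d <- ncol(Z)
  n <- nrow(X)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), d))
  best <- NULL
  best_ebic <- Inf
  for (r in seq_len(nrow(subsets))) {
    keep <- unlist(subsets[r, ])
    k <- sum(keep)
    dat <- data.frame(y = y)
    fit <- if (k == 0) {
      stats::glm(y ~ 1, data = dat, family = stats::binomial())
    } else {
      stats::glm(y ~ ., data = cbind(dat, as.data.frame(Z[, keep, drop = FALSE])),
                 family = stats::binomial())
    }
    ll <- as.numeric(stats::logLik(fit))
    ebic <- -2 * ll + k * log(n) + 2 * gamma * k * log(d)
    if (ebic < best_ebic) {
      best_ebic <- ebic
      best <- colnames(Z)[keep]
    }
  }
  list(support = best, ebic = best_ebic)
}

# ---- misc -------------------------------------------------------------------

tv_distance <- function(X, states, prob) {
  p <- ncol(states)
  key <- X %*% 2^(seq_len(p) - 1)
  emp <- tabulate(key + 1, nbins = 2^p) / nrow(X)
  exact <- numeric(2^p)
  exact[states %*% 2^(seq_len(p) - 1) + 1] <- prob
  0.5 * sum(abs(emp - exact))
}

# small ground truth for fast cohort tests: default truth, cheaper Gibbs
quick_cohort <- function(n, seed, truth = elsi_like_truth()) {
  generate_cohort(truth, n, seed = seed, burn_in = 200, thin = 2)
}

toy_pair_model <- function() {
  fixture_matrix(paste0("v", 1:4),
                 list(list("v1", "v2", 1.5), list("v3", "v4", 1.2)))
}
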