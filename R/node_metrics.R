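#' Node predictability (correct classification)
#'
#' For each node, predicts its value from its estimated neighbours by
#' thresholding the model's conditional probability
#' `logistic(tau_i + sum_j w_ij x_j)` at 0.5, and reports the in-sample
#' proportion correct (CC) together with the trivial benchmark
#' `CC_baseline = max(p, 1 - p)` achieved by always predicting the majority
#' class. An isolated node's CC equals its baseline by construction.
#'
#' @param X The binary matrix the network was estimated from.
#' @param network An `ising_network`.
#' @param newdata Optional held-out binary matrix: when supplied, CC and the
#'   baseline are evaluated out-of-sample on it instead of on `X`, removing
#'   the in-sample optimism.
#' @return `data.frame` with `node`, `cc`, `cc_baseline`.
#' @export
predictability_cc <- function(X, network, newdata = NULL) {
  X <- as.matrix(if (is.null(newdata)) X else newdata)
  nodes <- intersect(network$nodes, colnames(X))
  skipped <- setdiff(colnames(X), nodes)
  res <- lapply(nodes, function(nd) {
    others <- setdiff(network$nodes, nd)
    eta <- network$thresholds[nd] +
      X[, others, drop = FALSE] %*% network$weights[others, nd]
    pred <- as.integer(expit(eta) > 0.5)
    phat <- mean(X[, nd])
    data.frame(node = nd, cc = mean(pred == X[, nd]),
               cc_baseline = max(phat, 1 - phat),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (length(skipped)) attr(out, "skipped") <- skipped
  out
}

#' Centrality measures on a weighted network
#'
#' Computes, on absolute edge weights (negative Ising couplings carry no
#' distance semantics): strength (sum of absolute incident weights),
#' closeness with edge lengths 1/|w| using the reachable-set convention
#' `(n_reach - 1) / sum(d)` (0 for isolated nodes, so disconnected
#' stratified networks remain well-defined), shortest-path betweenness with
#' the same lengths, and — when a partition is supplied — the participation
#' coefficient \eqn{P_i = 1 - \sum_s (\kappa_{is}/\kappa_i)^2} measuring how
#' evenly a node's strength spreads over communities.
#'
#' @param network An `ising_network`.
#' @param partition Optional `community_partition` (or named membership
#'   vector) for the participation coefficient.
#' @return `data.frame` with `node`, `strength`, `closeness`, `betweenness`
#'   and, if a partition was given, `participation`.
#' @export
centralities <- function(network, partition = NULL) {
  A <- abs(network$weights)
  nodes <- network$nodes
  strength <- rowSums(A)
  g <- network_graph(network)
  len <- 1 / igraph::E(g)$weight
  D <- igraph::distances(g, weights = len)
  closeness <- vapply(seq_along(nodes), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (!length(d)) return(0)
    length(d) / sum(d)
  }, 0)
  betweenness <- if (igraph::ecount(g) > 0) {
    as.numeric(igraph::betweenness(g, weights = len, directed = FALSE))
  } else rep(0, length(nodes))
  out <- data.frame(node = nodes, strength = as.numeric(strength),
                    closeness = closeness, betweenness = betweenness,
                    stringsAsFactors = FALSE)
  if (!is.null(partition)) {
    memb <- if (inherits(partition, "community_partition")) {
      partition$membership
    } else partition
    memb <- memb[nodes]
    out$participation <- vapply(seq_along(nodes), function(i) {
      k_i <- strength[i]
      if (k_i == 0) return(0)
      k_is <- tapply(A[i, ], memb, sum)
      1 - sum((k_is / k_i)^2)
    }, 0)
  }
  rownames(out) <- NULL
  out
}

#' Centrality z-scores for plotting
#'
#' Standardises each centrality column of a [centralities()] table to zero
#' mean and unit variance across nodes (a constant column maps to 0) — the
#' usual scale for centrality profile plots.
#'
#' @param metrics Output of [centralities()] or [node_metrics()].
#' @return The table with the centrality columns replaced by z-scores.
#' @export
centrality_zscores <- function(metrics) {
  for (col in intersect(c("strength", "closeness", "betweenness",
                          "participation"), names(metrics))) {
    s <- stats::sd(metrics[[col]])
    m <- mean(metrics[[col]])
    metrics[[col]] <- if (isTRUE(s > 0)) (metrics[[col]] - m) / s
                      else rep(0, nrow(metrics))
  }
  metrics
}

#' Combined per-node metrics table
#'
#' Convenience wrapper joining [predictability_cc()] and [centralities()].
#'
#' @inheritParams predictability_cc
#' @inheritParams centralities
#' @return `data.frame` with one row per retained node.
#' @export
node_metrics <- function(X, network, partition = NULL) {
  merge(predictability_cc(X, network), centralities(network, partition),
        by = "node", sort = FALSE)
}
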