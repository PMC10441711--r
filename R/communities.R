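network_graph <- function(network) {
  A <- abs(network$weights)
  igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Walktrap community detection on an estimated network
#'
#' Runs the Walktrap algorithm (short random walks tend to stay inside
#' communities; merge agglomeratively, cut at maximal modularity) on the
#' absolute edge weights of an Ising network. Absolute values are needed
#' because walk probabilities must be nonnegative; the sign of an edge is
#' therefore ignored by the community structure. Isolated nodes become
#' singleton communities, and an empty network yields all singletons with
#' modularity 0.
#'
#' @param network An `ising_network`.
#' @param steps Random-walk length t (default 4).
#' @return Object of class `community_partition`: named integer
#'   `membership` (community ids 1..k), `modularity`, `steps`, `method`.
#' @export
walktrap_communities <- function(network, steps = 4) {
  g <- network_graph(network)
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  membership <- integer(n)
  names(membership) <- network$nodes
  if (igraph::ecount(g) == 0) {
    membership[] <- seq_len(n)
    return(structure(list(membership = membership, modularity = 0,
                          steps = steps, method = "walktrap"),
                     class = "community_partition"))
  }
  # walktrap is run per connected component; isolated nodes are singletons
  comp <- igraph::components(g)
  next_id <- 0L
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    if (length(vs) == 1 || sum(deg[vs]) == 0) {
      membership[vs] <- next_id + 1L
      next_id <- next_id + 1L
      next
    }
    sg <- igraph::induced_subgraph(g, vs)
    wt <- igraph::cluster_walktrap(sg, weights = igraph::E(sg)$weight,
                                   steps = steps)
    m <- igraph::membership(wt)
    membership[vs] <- next_id + as.integer(m)
    next_id <- next_id + max(as.integer(m))
  }
  Q <- igraph::modularity(g, membership, weights = igraph::E(g)$weight)
  structure(list(membership = membership, modularity = Q, steps = steps,
                 method = "walktrap"),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("Community partition (", x$method, ", t = ", x$steps, "): ",
      length(unique(x$membership)), " communities, Q = ",
      round(x$modularity, 4), "\n", sep = "")
  invisible(x)
}

# Optimal relabelling of `membership` onto `reference` by maximum overlap.
# For up to 8 labels the assignment problem is solved exactly by permutation
# enumeration; beyond that a greedy matching is used. Returns the relabelled
# membership (labels of `reference` where matched; fresh labels otherwise).
align_partition <- function(reference, membership) {
  common <- intersect(names(reference), names(membership))
  ref <- reference[common]
  mem <- membership[common]
  ref_labs <- sort(unique(ref))
  mem_labs <- sort(unique(mem))
  overlap <- outer(mem_labs, ref_labs,
                   Vectorize(function(a, b) sum(mem == a & ref == b)))
  k <- length(mem_labs)
  r <- length(ref_labs)
  assign_to <- rep(NA_integer_, k)
  if (k <= 8 && r <= 8) {
    # pad to square with zero columns, enumerate permutations
    m <- max(k, r)
    M <- matrix(0, m, m)
    M[seq_len(k), seq_len(r)] <- overlap
    perms <- permutations_of(m)
    best <- -1; bestp <- NULL
    for (pi in seq_len(nrow(perms))) {
      s <- sum(M[cbind(seq_len(m), perms[pi, ])])
      if (s > best) { best <- s; bestp <- perms[pi, ] }
    }
    assign_to <- ifelse(bestp[seq_len(k)] <= r, bestp[seq_len(k)], NA)
  } else {
    ov <- overlap
    for (step in seq_len(min(k, r))) {
      idx <- which(ov == max(ov), arr.ind = TRUE)[1, ]
      if (ov[idx[1], idx[2]] < 0) break
      assign_to[idx[1]] <- idx[2]
      ov[idx[1], ] <- -1
      ov[, idx[2]] <- -1
    }
  }
  new_lab <- integer(length(mem_labs))
  next_free <- max(ref_labs) + 1L
  for (i in seq_len(k)) {
    if (!is.na(assign_to[i])) {
      new_lab[i] <- ref_labs[assign_to[i]]
    } else {
      new_lab[i] <- next_free
      next_free <- next_free + 1L
    }
  }
  out <- new_lab[match(membership, mem_labs)]
  names(out) <- names(membership)
  out
}

permutations_of <- function(m) {
  if (m == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(m - 1L)
  out <- matrix(0L, m * nrow(sub), m)
  row <- 1L
  for (i in seq_len(m)) {
    rest <- setdiff(seq_len(m), i)
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(i, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}

#' Bootstrap stability of community structure
#'
#' Re-estimates the network and its Walktrap partition on `n_boot` row
#' resamples (with replacement, same n), aligns each bootstrap partition to
#' the original by maximum-overlap label matching, and summarises per-node
#' membership stability. The consensus is the per-node modal aligned label
#' (ties broken by a seeded uniform draw); the median over aligned integer
#' labels is reported alongside. Per-bootstrap eigenvalues of the modularity
#' matrix of the absolute-weight network are retained as an additional
#' stability diagnostic.
#'
#' The partition is flagged unstable when the original network carries no
#' real community signal (modularity below `q_floor`, or an all-singleton /
#' single-community partition) or when mean per-node agreement with the
#' consensus falls below `agreement_floor`.
#'
#' @param X Binary node matrix for one stratum (see [network_matrix()]).
#' @param n_boot Number of bootstrap resamples (default 100).
#' @param seed Integer seed.
#' @param steps Walktrap walk length.
#' @param agreement_floor,q_floor Stability flags (defaults 0.8 and 0.05).
#' @inheritParams fit_nodewise_lasso
#' @inheritParams assemble_network
#' @return Object of class `community_stability`.
#' @export
community_bootstrap <- function(X, n_boot = 100, seed = NULL, steps = 4,
                                gamma = 0.25, rule = "AND", nlambda = 100,
                                lambda_min_ratio = 0.01,
                                agreement_floor = 0.8, q_floor = 0.05) {
  if (n_boot < 1) stop("n_boot must be at least 1")
  X <- as.matrix(X)
  net0 <- estimate_ising_network(X, gamma = gamma, rule = rule,
                                 nlambda = nlambda,
                                 lambda_min_ratio = lambda_min_ratio)
  part0 <- walktrap_communities(net0, steps = steps)
  nodes <- colnames(X)
  M <- matrix(NA_integer_, n_boot, length(nodes),
              dimnames = list(NULL, nodes))
  eigs <- vector("list", n_boot)
  seeds <- substream_seeds(seed, n_boot + 1L)
  n <- nrow(X)
  for (b in seq_len(n_boot)) {
    Xb <- with_seed(seeds[b], X[sample.int(n, n, replace = TRUE), ,
                                drop = FALSE])
    netb <- tryCatch(
      estimate_ising_network(Xb, gamma = gamma, rule = rule,
                             nlambda = nlambda,
                             lambda_min_ratio = lambda_min_ratio),
      error = function(e) NULL)
    if (is.null(netb)) next
    partb <- walktrap_communities(netb, steps = steps)
    aligned <- align_partition(part0$membership, partb$membership)
    M[b, names(aligned)] <- aligned
    eigs[[b]] <- sort(modularity_eigenvalues(netb), decreasing = TRUE)
  }
  consensus <- with_seed(seeds[n_boot + 1L], {
    vapply(nodes, function(nd) {
      v <- M[, nd]
      v <- v[!is.na(v)]
      if (!length(v)) return(NA_integer_)
      tb <- table(v)
      modal <- as.integer(names(tb)[tb == max(tb)])
      if (length(modal) > 1) modal <- sample(modal, 1)  # seeded tie-break
      modal
    }, integer(1))
  })
  median_label <- apply(M, 2, function(v) stats::median(v, na.rm = TRUE))
  agreement <- vapply(nodes, function(nd) {
    v <- M[, nd]
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    mean(v == consensus[nd])
  }, 0)
  k <- length(unique(part0$membership))
  degenerate <- k <= 1 || k >= length(nodes) || part0$modularity < q_floor
  stable <- !degenerate && mean(agreement, na.rm = TRUE) >= agreement_floor
  structure(
    list(original = part0, network = net0, membership = M,
         consensus = consensus, median_label = median_label,
         agreement = agreement, eigen_summary = eigs, n_boot = n_boot,
         stable = stable,
         reason = if (degenerate) "no community signal in original network"
                  else if (!stable) "low bootstrap agreement" else "stable"),
    class = "community_stability"
  )
}

modularity_eigenvalues <- function(network) {
  A <- abs(network$weights)
  k <- rowSums(A)
  m2 <- sum(k)
  if (m2 == 0) return(rep(0, nrow(A)))
  B <- A - outer(k, k) / m2
  eigen(B, symmetric = TRUE, only.values = TRUE)$values
}

#' @export
print.community_stability <- function(x, ...) {
  cat("Community bootstrap (", x$n_boot, " resamples): mean agreement ",
      round(mean(x$agreement, na.rm = TRUE), 3), "; ",
      if (x$stable) "stable" else paste0("UNSTABLE (", x$reason, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Human-readable community labels
#'
#' Attaches stable names to community ids, either from a user map
#' (`community id -> label`) or automatically by concatenating member node
#' names. The output is invariant to a relabelling permutation of the ids.
#'
#' @param partition A `community_partition`.
#' @param naming Optional named character vector mapping community ids to
#'   labels.
#' @return Named character vector: one label per community, names are
#'   community ids, ordered by id.
#' @export
name_communities <- function(partition, naming = NULL) {
  ids <- sort(unique(partition$membership))
  labels <- vapply(ids, function(id) {
    if (!is.null(naming) && as.character(id) %in% names(naming)) {
      return(naming[[as.character(id)]])
    }
    paste(sort(names(partition$membership)[partition$membership == id]),
          collapse = "–")
  }, "")
  stats::setNames(labels, ids)
}
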