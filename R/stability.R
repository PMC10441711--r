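edge_names <- function(nodes) {
  idx <- which(upper.tri(diag(length(nodes))), arr.ind = TRUE)
  paste(nodes[idx[, 1]], nodes[idx[, 2]], sep = "--")
}

edge_vector <- function(network, nodes) {
  W <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  common <- intersect(nodes, network$nodes)
  W[common, common] <- network$weights[common, common]
  stats::setNames(W[upper.tri(W)], edge_names(nodes))
}

#' Nonparametric bootstrap of edge weights
#'
#' Re-estimates the network on `B` row resamples (with replacement, same n)
#' and forms per-edge 2.5%/97.5% quantile intervals around the original
#' estimate, the standard accuracy check for eLASSO networks. Replicates
#' whose estimation fails are recorded and excluded; more than
#' `max_fail_frac` failures is an error.
#'
#' @param X Binary node matrix for one stratum.
#' @param B Number of resamples (default 500).
#' @param seed Integer seed.
#' @param max_fail_frac Tolerated replicate failure fraction (default 0.1).
#' @inheritParams fit_nodewise_lasso
#' @inheritParams assemble_network
#' @return Object of class `bootstrap_ensemble`: `kind`, replicate x edge
#'   matrix `edges`, `original` edge vector, `ci` data.frame (edge, lower,
#'   upper, original), failure count.
#' @export
nonparametric_bootstrap <- function(X, B = 500, seed = NULL, gamma = 0.25,
                                    rule = "AND", nlambda = 100,
                                    lambda_min_ratio = 0.01,
                                    max_fail_frac = 0.1) {
  X <- as.matrix(X)
  net0 <- estimate_ising_network(X, gamma = gamma, rule = rule,
                                 nlambda = nlambda,
                                 lambda_min_ratio = lambda_min_ratio)
  nodes <- colnames(X)
  orig <- edge_vector(net0, nodes)
  E <- matrix(NA_real_, B, length(orig), dimnames = list(NULL, names(orig)))
  seeds <- substream_seeds(seed, B)
  n <- nrow(X)
  failures <- 0L
  for (b in seq_len(B)) {
    Xb <- with_seed(seeds[b], X[sample.int(n, n, replace = TRUE), ,
                                drop = FALSE])
    netb <- tryCatch(
      estimate_ising_network(Xb, gamma = gamma, rule = rule,
                             nlambda = nlambda,
                             lambda_min_ratio = lambda_min_ratio),
      error = function(e) NULL)
    if (is.null(netb)) { failures <- failures + 1L; next }
    E[b, ] <- edge_vector(netb, nodes)
  }
  if (failures > max_fail_frac * B) {
    stop(failures, " of ", B, " bootstrap replicates failed estimation")
  }
  qs <- apply(E, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  ci <- data.frame(edge = names(orig), lower = qs[1, ], upper = qs[2, ],
                   original = as.numeric(orig), stringsAsFactors = FALSE)
  rownames(ci) <- NULL
  structure(list(kind = "nonparametric", B = B, edges = E, original = orig,
                 ci = ci, network = net0, failures = failures),
            class = "bootstrap_ensemble")
}

#' @export
print.bootstrap_ensemble <- function(x, ...) {
  cat("Edge-weight bootstrap: B = ", x$B, " (", x$failures, " failed), ",
      length(x$original), " edges\n", sep = "")
  invisible(x)
}

#' Bootstrap difference test between two edges
#'
#' Declares the magnitudes of two edges distinguishable when the 95%
#' bootstrap quantile interval of their weight difference excludes zero.
#'
#' @param ensemble A `bootstrap_ensemble`.
#' @param edge_a,edge_b Edge names (`"nodeA--nodeB"`).
#' @param level Confidence level (default 0.95).
#' @return List with `significant`, `ci`, `difference` (original-estimate
#'   difference).
#' @export
edge_difference_test <- function(ensemble, edge_a, edge_b, level = 0.95) {
  for (e in c(edge_a, edge_b)) {
    if (!e %in% colnames(ensemble$edges)) stop("edge not indexed: ", e)
  }
  d <- ensemble$edges[, edge_a] - ensemble$edges[, edge_b]
  d <- d[!is.na(d)]
  alpha <- (1 - level) / 2
  ci <- stats::quantile(d, c(alpha, 1 - alpha), names = FALSE)
  list(significant = ci[1] > 0 || ci[2] < 0, ci = ci,
       difference = unname(ensemble$original[edge_a] -
                             ensemble$original[edge_b]))
}

#' Case-dropping bootstrap and CS-coefficients for centralities
#'
#' For each retained-case proportion q in `proportions`, draws `B`
#' subsamples of size `floor(q * n)` without replacement, re-estimates the
#' network, recomputes the chosen centralities, and correlates them
#' (Spearman, over nodes) with the original values. The CS-coefficient of a
#' measure is the largest case-drop proportion (1 - q) such that the
#' correlation stays at or above `cor_threshold` in at least `conf` of the
#' subsamples at every drop up to it. By the usual interpretability
#' convention, CS below 0.25 is unstable and 0.5 or more is desirable; the
#' grid caps what can be observed, so the value is reported together with
#' `bounded` flags.
#'
#' @param X Binary node matrix for one stratum.
#' @param measures Centralities to track (subset of `"strength"`,
#'   `"closeness"`, `"betweenness"`).
#' @param proportions Retained-case proportions (default 0.9 down to 0.3 by
#'   0.1, plus 0.25).
#' @param B Subsamples per proportion (default 500). With
#'   `total_budget = TRUE`, `B` is the total across proportions.
#' @param cor_threshold,conf CS definition constants (0.7 and 0.95).
#' @param seed Integer seed.
#' @inheritParams fit_nodewise_lasso
#' @inheritParams assemble_network
#' @return Object of class `cs_result`: per-measure CS value with bound
#'   flags, and the full proportion x replicate correlation array.
#' @export
case_dropping_cs <- function(X, measures = c("strength", "closeness",
                                             "betweenness"),
                             proportions = c(seq(0.9, 0.3, by = -0.1), 0.25),
                             B = 500, cor_threshold = 0.7, conf = 0.95,
                             seed = NULL, gamma = 0.25, rule = "AND",
                             nlambda = 100, lambda_min_ratio = 0.01,
                             total_budget = FALSE) {
  measures <- match.arg(measures, several.ok = TRUE)
  if (!length(proportions)) stop("proportions grid is empty")
  proportions <- sort(proportions, decreasing = TRUE)
  X <- as.matrix(X)
  n <- nrow(X)
  if (floor(min(proportions) * n) < 10) {
    stop("n too small for the smallest retained proportion")
  }
  if (total_budget) B <- max(1L, floor(B / length(proportions)))
  net0 <- estimate_ising_network(X, gamma = gamma, rule = rule,
                                 nlambda = nlambda,
                                 lambda_min_ratio = lambda_min_ratio)
  cent0 <- centralities(net0)
  nodes <- colnames(X)
  cors <- array(NA_real_, dim = c(length(proportions), B, length(measures)),
                dimnames = list(paste0("q", proportions), NULL, measures))
  seeds <- substream_seeds(seed, length(proportions) * B)
  s <- 0L
  for (qi in seq_along(proportions)) {
    m <- floor(proportions[qi] * n)
    for (b in seq_len(B)) {
      s <- s + 1L
      Xs <- with_seed(seeds[s], X[sample.int(n, m), , drop = FALSE])
      nets <- tryCatch(
        estimate_ising_network(Xs, gamma = gamma, rule = rule,
                               nlambda = nlambda,
                               lambda_min_ratio = lambda_min_ratio),
        error = function(e) NULL)
      if (is.null(nets)) next
      cents <- centralities(nets)
      common <- intersect(cent0$node, cents$node)
      for (ms in measures) {
        a <- cent0[[ms]][match(common, cent0$node)]
        bb <- cents[[ms]][match(common, cents$node)]
        if (stats::sd(a) == 0 || stats::sd(bb) == 0) {
          # degenerate centrality vector: correlation undefined, count as 0
          cors[qi, b, ms] <- 0
        } else {
          cors[qi, b, ms] <- stats::cor(a, bb, method = "spearman")
        }
      }
    }
  }
  drops <- 1 - proportions
  cs <- lapply(measures, function(ms) {
    ok <- vapply(seq_along(proportions), function(qi) {
      v <- cors[qi, , ms]
      v <- v[!is.na(v)]
      if (!length(v)) return(FALSE)
      mean(v >= cor_threshold) >= conf
    }, logical(1))
    # largest drop such that every smaller drop also satisfies the rule
    run <- cumprod(ok) == 1
    if (!any(run)) {
      list(cs = 0, bounded = "below", note = paste0("< ", min(drops)))
    } else {
      val <- max(drops[run])
      list(cs = val,
           bounded = if (val == max(drops)) "above" else "exact",
           note = if (val == max(drops)) paste0(">= ", val) else
             as.character(val))
    }
  })
  names(cs) <- measures
  structure(list(cs = cs, correlations = cors, proportions = proportions,
                 B = B, cor_threshold = cor_threshold, conf = conf,
                 network = net0, original = cent0),
            class = "cs_result")
}

#' @export
print.cs_result <- function(x, ...) {
  cat("CS-coefficients (cor >= ", x$cor_threshold, " with prob >= ",
      x$conf, "):\n", sep = "")
  for (ms in names(x$cs)) {
    cat("  ", format(ms, width = 12), " CS = ", x$cs[[ms]]$note, "\n",
        sep = "")
  }
  invisible(x)
}

#' Tidy CS table
#' @param x A `cs_result`.
#' @return `data.frame` with `measure`, `cs`, `bounded`.
#' @export
cs_table <- function(x) {
  data.frame(measure = names(x$cs),
             cs = vapply(x$cs, function(z) z$cs, 0),
             bounded = vapply(x$cs, function(z) z$bounded, ""),
             stringsAsFactors = FALSE, row.names = NULL)
}
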