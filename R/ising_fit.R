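#' Nodewise L1-penalised logistic regression with EBIC selection
#'
#' The eLASSO building block: regresses one binary node on all remaining
#' columns over a decreasing lambda grid (coordinate descent, intercept
#' unpenalised, warm starts), and scores every grid point with the extended
#' BIC \deqn{EBIC_\gamma(\lambda) = -2\ell + k \log n + 2\gamma k \log(p-1)}
#' where k counts non-zero coefficients (intercept excluded). The selected
#' model minimises EBIC on the grid.
#'
#' @param X Binary 0/1 matrix (n x p) with column names.
#' @param node Column index or name of the response node.
#' @param lambda Optional decreasing lambda grid; by default 100 log-spaced
#'   values from the data-derived `lambda_max` (the smallest lambda zeroing
#'   every coefficient) down to `lambda_min_ratio * lambda_max`.
#' @param nlambda,lambda_min_ratio Grid size and lower end (as a fraction of
#'   `lambda_max`).
#' @param gamma EBIC hyperparameter (0.25 by default).
#' @return An object of class `ebic_path`: the grid, coefficient matrix,
#'   intercepts, per-lambda log pseudo-likelihood, non-zero counts, EBIC
#'   values, selected index, and the smooth-part gradient at each solution
#'   (for optimality checks).
#' @export
fit_nodewise_lasso <- function(X, node, lambda = NULL, nlambda = 100,
                               lambda_min_ratio = 0.01, gamma = 0.25) {
  X <- as.matrix(X)
  if (!all(X %in% c(0, 1))) stop("X must be binary 0/1")
  if (is.character(node)) node <- match(node, colnames(X))
  y <- X[, node]
  if (length(unique(y)) < 2) {
    stop("node column is constant; flag it for dropping")
  }
  Z <- X[, -node, drop = FALSE]
  n <- nrow(X)
  d <- ncol(Z)
  if (is.null(lambda)) {
    ybar <- mean(y)
    # smallest lambda with an all-zero solution; inflated a hair so the
    # first grid point sits strictly at the null model (boundary rounding
    # must not let a zero-size coefficient enter with df = 1)
    lambda_max <- max(abs(crossprod(Z, y - ybar)) / n) * (1 + 1e-6)
    lambda_max <- max(lambda_max, 1e-4)
    lambda <- exp(seq(log(lambda_max), log(lambda_min_ratio * lambda_max),
                      length.out = nlambda))
  }
  if (is.unsorted(rev(lambda))) stop("lambda grid must be decreasing")
  fit <- logistic_lasso_path_cpp(Z, as.integer(y), lambda,
                                 tol = 1e-6, max_outer = 40L,
                                 max_inner = 100L)
  ebic <- -2 * fit$loglik + fit$df * log(n) + 2 * gamma * fit$df * log(d)
  sel <- which.min(ebic)
  structure(
    list(node = colnames(X)[node], predictors = colnames(Z),
         lambda = lambda, beta = fit$beta, intercept = fit$intercept,
         loglik = fit$loglik, df = fit$df, ebic = ebic, grad = fit$grad,
         selected = sel, gamma = gamma, n = n),
    class = "ebic_path"
  )
}

#' @export
print.ebic_path <- function(x, ...) {
  cat("eLASSO path for node '", x$node, "': ", length(x$lambda),
      " lambdas, selected df = ", x$df[x$selected],
      " (EBIC = ", round(x$ebic[x$selected], 2), ", gamma = ", x$gamma,
      ")\n", sep = "")
  invisible(x)
}

selected_coefs <- function(path) {
  b <- path$beta[, path$selected]
  names(b) <- path$predictors
  b
}

#' Assemble a symmetric Ising network from nodewise fits
#'
#' Combines the per-node EBIC-selected logistic coefficients into one
#' symmetric weighted network. Under the default AND rule an edge i-j is
#' kept only when both directed coefficients are non-zero; under OR when
#' either is. The edge weight is the mean of the two directed coefficients
#' (with 0 standing in for an absent direction under OR). Thresholds are
#' the selected intercepts.
#'
#' @param paths List of `ebic_path` objects, one per retained node.
#' @param rule `"AND"` (default) or `"OR"`.
#' @param dropped_nodes Optional named character vector of dropped nodes
#'   (name = node, value = reason), recorded in the result.
#' @return Object of class `ising_network` with fields `nodes`, `weights`
#'   (symmetric matrix), `thresholds`, `gamma`, `n`, `rule`,
#'   `dropped_nodes`.
#' @export
assemble_network <- function(paths, rule = c("AND", "OR"),
                             dropped_nodes = character(0)) {
  rule <- match.arg(rule)
  nodes <- vapply(paths, `[[`, "", "node")
  for (p in paths) {
    if (!setequal(p$predictors, setdiff(nodes, p$node))) {
      stop("inconsistent node sets across nodewise fits")
    }
  }
  p <- length(nodes)
  B <- matrix(0, p, p, dimnames = list(nodes, nodes))
  for (k in seq_len(p)) {
    B[nodes[k], paths[[k]]$predictors] <- selected_coefs(paths[[k]])
  }
  W <- (B + t(B)) / 2
  present <- if (rule == "AND") (B != 0) & (t(B) != 0) else (B != 0) | (t(B) != 0)
  W[!present] <- 0
  diag(W) <- 0
  thresholds <- vapply(paths, function(p) p$intercept[p$selected], 0)
  names(thresholds) <- nodes
  structure(
    list(nodes = nodes, weights = W, thresholds = thresholds,
         gamma = paths[[1]]$gamma, n = paths[[1]]$n, rule = rule,
         dropped_nodes = dropped_nodes),
    class = "ising_network"
  )
}

#' @export
print.ising_network <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat("Ising network: ", length(x$nodes), " nodes, ", ne, " edges (",
      x$rule, " rule, gamma = ", x$gamma, ", n = ", x$n, ")\n", sep = "")
  if (length(x$dropped_nodes)) {
    cat("dropped:", paste(names(x$dropped_nodes), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Estimate an Ising network by eLASSO
#'
#' Runs [fit_nodewise_lasso()] for every column of a binary data matrix and
#' symmetrises with [assemble_network()]. Constant columns cannot be
#' regressed and are dropped with a recorded reason.
#'
#' @inheritParams fit_nodewise_lasso
#' @inheritParams assemble_network
#' @return An `ising_network`.
#' @export
estimate_ising_network <- function(X, gamma = 0.25, rule = c("AND", "OR"),
                                   nlambda = 100, lambda_min_ratio = 0.01) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  const <- apply(X, 2, function(col) length(unique(col)) < 2)
  dropped <- character(0)
  if (any(const)) {
    dropped <- stats::setNames(paste0("constant column (all ", X[1, const], ")"),
                               colnames(X)[const])
    X <- X[, !const, drop = FALSE]
  }
  if (ncol(X) < 2) stop("fewer than two non-constant nodes")
  paths <- lapply(seq_len(ncol(X)), function(j) {
    fit_nodewise_lasso(X, j, nlambda = nlambda,
                       lambda_min_ratio = lambda_min_ratio, gamma = gamma)
  })
  assemble_network(paths, rule = rule, dropped_nodes = dropped)
}

#' Per-stratum disease-hospitalisation networks
#'
#' Builds, for each of the five marginal strata (female, male, and the
#' three age bands), the 20-node binary matrix of the 19 conditions plus
#' hospitalisation, and estimates one network per stratum. Strata smaller
#' than `min_n` are skipped with a warning; constant nodes within a stratum
#' (e.g. rare diseases in the oldest band) are dropped and recorded.
#'
#' @param table Complete-case cohort table.
#' @param min_n Minimum stratum size (default 200).
#' @inheritParams fit_nodewise_lasso
#' @inheritParams assemble_network
#' @return Named list of `ising_network` objects.
#' @export
estimate_stratified_networks <- function(table, min_n = 200, gamma = 0.25,
                                         rule = c("AND", "OR"),
                                         nlambda = 100,
                                         lambda_min_ratio = 0.01) {
  rule <- match.arg(rule)
  strata <- stratify(table, "network")
  out <- list()
  for (nm in names(strata)) {
    sub <- strata[[nm]]
    if (nrow(sub) < min_n) {
      warning("stratum '", nm, "' has n = ", nrow(sub), " < ", min_n,
              "; skipped")
      next
    }
    X <- network_matrix(sub)
    out[[nm]] <- estimate_ising_network(X, gamma = gamma, rule = rule,
                                        nlambda = nlambda,
                                        lambda_min_ratio = lambda_min_ratio)
  }
  out
}

#' Binary node matrix (19 conditions + hospitalisation) for network fitting
#' @param table Complete-case cohort table.
#' @return Integer 0/1 matrix with 20 named columns.
#' @export
network_matrix <- function(table) {
  X <- as.matrix(table[, c(disease_catalog(), "hospitalised")])
  storage.mode(X) <- "integer"
  if (anyNA(X)) stop("network matrix contains missing values")
  X
}
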