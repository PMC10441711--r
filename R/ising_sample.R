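#' Ising model samplers on the \{0,1\} domain
#'
#' The package uses throughout the binary Ising model on \eqn{x \in \{0,1\}^p}
#' \deqn{P(x) \propto \exp\left(\sum_i \tau_i x_i + \sum_{i<j} w_{ij} x_i x_j\right)}
#' whose full conditionals are logistic regressions,
#' \eqn{P(x_i = 1 \mid x_{-i}) = \mathrm{logistic}(\tau_i + \sum_j w_{ij} x_j)}.
#' `sample_ising_exact()` enumerates all \eqn{2^p} states (feasible up to
#' p = 16) and draws i.i.d. samples from the exact distribution;
#' `sample_ising_gibbs()` runs a single-site Gibbs sampler and scales to the
#' 19-disease graphs used by the cohort generator.
#'
#' @param weights Symmetric p x p coupling matrix with zero diagonal.
#' @param thresholds Length-p vector of per-node thresholds \eqn{\tau_i}.
#' @param n Number of draws.
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return Integer matrix (n x p) of 0/1 draws; columns named after
#'   `rownames(weights)` when present.
#' @seealso [ising_state_probs()] for the enumerated distribution.
#' @export
sample_ising_exact <- function(weights, thresholds, n, seed = NULL) {
  check_ising_model(weights, thresholds)
  p <- ncol(weights)
  if (p > 16) {
    stop("exact enumeration limited to p <= 16 nodes; use sample_ising_gibbs()")
  }
  if (n <= 0) stop("n must be positive")
  sp <- ising_state_probs(weights, thresholds)
  idx <- with_seed(seed, {
    sample.int(nrow(sp$states), size = n, replace = TRUE, prob = sp$prob)
  })
  out <- sp$states[idx, , drop = FALSE]
  colnames(out) <- rownames(weights)
  out
}

#' @param burn_in Number of discarded initial Gibbs sweeps.
#' @param thin Keep one draw every `thin` sweeps.
#' @rdname sample_ising_exact
#' @export
sample_ising_gibbs <- function(weights, thresholds, n, burn_in = 1000,
                               thin = 10, seed = NULL) {
  check_ising_model(weights, thresholds)
  if (n <= 0) stop("n must be positive")
  if (burn_in < 0 || thin < 1) stop("burn_in must be >= 0 and thin >= 1")
  out <- with_seed(seed, {
    gibbs_sample_cpp(weights, thresholds, as.integer(n),
                     as.integer(burn_in), as.integer(thin))
  })
  colnames(out) <- rownames(weights)
  out
}

#' Exact state distribution of a small Ising model
#'
#' Enumerates all \eqn{2^p} binary states and their probabilities. Used as
#' the reference distribution the Gibbs sampler must agree with.
#'
#' @inheritParams sample_ising_exact
#' @return List with `states` (2^p x p 0/1 matrix) and `prob`.
#' @export
ising_state_probs <- function(weights, thresholds) {
  check_ising_model(weights, thresholds)
  p <- ncol(weights)
  if (p > 16) stop("enumeration limited to p <= 16")
  states <- as.matrix(expand.grid(rep(list(0:1), p)))
  dimnames(states) <- list(NULL, rownames(weights))
  logw <- states %*% thresholds + 0.5 * rowSums((states %*% weights) * states)
  logw <- logw - max(logw)
  prob <- exp(logw) / sum(exp(logw))
  list(states = states, prob = as.numeric(prob))
}

check_ising_model <- function(weights, thresholds) {
  if (!is.matrix(weights) || nrow(weights) != ncol(weights)) {
    stop("weights must be a square matrix")
  }
  if (!isTRUE(all.equal(weights, t(weights), tolerance = 1e-10))) {
    stop("weights must be symmetric")
  }
  if (any(diag(weights) != 0)) stop("weights must have a zero diagonal")
  if (length(thresholds) != ncol(weights)) {
    stop("thresholds length must equal the number of nodes")
  }
  if (any(!is.finite(weights)) || any(!is.finite(thresholds))) {
    stop("weights and thresholds must be finite")
  }
  invisible(TRUE)
}
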