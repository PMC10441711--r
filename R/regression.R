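#' Survey-weighted Poisson prevalence-ratio model
#'
#' Fits a log-link Poisson working model for a binary outcome with
#' per-person weights (combined survey x IPW weights) and reports prevalence
#' ratios with robust (sandwich) 95% confidence intervals. The Poisson
#' pseudo-likelihood deliberately misspecifies the Bernoulli variance, so
#' the sandwich estimator \eqn{B^{-1} M B^{-1}} is mandatory, with B the
#' weighted information and M the weighted outer product of score
#' contributions.
#'
#' @param data Cohort table.
#' @param outcome Name of a binary 0/1 column.
#' @param covariates Character vector of factor covariates (e.g.
#'   `c("sex", "age_group")`).
#' @param weights Optional numeric vector or column name; defaults to
#'   `combined_weight` when present, otherwise unit weights.
#' @return A `data.frame` with one row per covariate level (reference levels
#'   included, with `estimate = 1`): `outcome`, `term`, `level`,
#'   `reference`, `estimate` (PR), `ci_low`, `ci_high`, `se_log`.
#' @export
fit_weighted_poisson_pr <- function(data, outcome, covariates,
                                    weights = NULL) {
  w <- resolve_weights(data, weights)
  y <- data[[outcome]]
  if (is.null(y)) stop("unknown outcome column: ", outcome)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  covariates <- drop_empty_covariates(data, covariates)
  dat <- data[, covariates, drop = FALSE]
  dat$.y <- y
  dat$.w <- w
  dat <- droplevels(dat)
  form <- stats::as.formula(paste(".y ~", paste(covariates, collapse = " + ")))
  fit <- suppressWarnings(
    stats::glm(form, data = dat, family = stats::poisson(link = "log"),
               weights = .w)
  )
  if (!fit$converged) stop("Poisson fit did not converge")
  tidy_fit(fit, dat, covariates, outcome, exponentiate = TRUE,
           vcov_mat = sandwich::vcovHC(fit, type = "HC0"))
}

#' Weighted linear models with robust standard errors
#'
#' Weighted least squares for the numeric outcomes measured on hospitalised
#' persons (readmission count, length of stay in days), with
#' heteroscedasticity-robust HC1 standard errors by default and normal-based
#' 95% confidence intervals.
#'
#' @inheritParams fit_weighted_poisson_pr
#' @param outcome Name of a numeric column (`readmissions` or
#'   `length_of_stay`).
#' @param robust `"HC1"` (default) or `"classical"`.
#' @return As [fit_weighted_poisson_pr()], with `estimate` a beta
#'   coefficient and reference levels at 0.
#' @export
fit_weighted_linear <- function(data, outcome, covariates, weights = NULL,
                                robust = c("HC1", "classical")) {
  robust <- match.arg(robust)
  w <- resolve_weights(data, weights)
  y <- data[[outcome]]
  if (is.null(y) || !is.numeric(y)) stop("outcome must be a numeric column")
  covariates <- drop_empty_covariates(data, covariates)
  dat <- data[, covariates, drop = FALSE]
  dat$.y <- y
  dat$.w <- w
  dat <- droplevels(dat)
  form <- stats::as.formula(paste(".y ~", paste(covariates, collapse = " + ")))
  fit <- stats::lm(form, data = dat, weights = .w)
  if (fit$df.residual <= 0) stop("not enough observations for the design")
  V <- if (robust == "HC1") sandwich::vcovHC(fit, type = "HC1")
       else stats::vcov(fit)
  tidy_fit(fit, dat, covariates, outcome, exponentiate = FALSE, vcov_mat = V)
}

resolve_weights <- function(data, weights) {
  if (is.null(weights)) {
    if (!is.null(data$combined_weight)) return(data$combined_weight)
    return(rep(1, nrow(data)))
  }
  if (is.character(weights)) {
    if (is.null(data[[weights]])) stop("unknown weight column: ", weights)
    return(data[[weights]])
  }
  stopifnot(is.numeric(weights), length(weights) == nrow(data))
  weights
}

drop_empty_covariates <- function(data, covariates) {
  keep <- vapply(covariates, function(v) {
    x <- droplevels(as.factor(data[[v]]))
    nlevels(x) >= 2
  }, logical(1))
  if (any(!keep)) {
    warning("dropping covariate(s) with a single occupied level: ",
            paste(covariates[!keep], collapse = ", "))
  }
  if (!any(keep)) stop("no covariate has two occupied levels")
  covariates[keep]
}

# Tidy a glm/lm fit into one row per covariate level, adding explicit
# reference-level rows (PR = 1 or beta = 0).
tidy_fit <- function(fit, dat, covariates, outcome, exponentiate, vcov_mat) {
  est <- stats::coef(fit)
  se <- sqrt(diag(vcov_mat))
  rows <- list()
  for (v in covariates) {
    levs <- levels(droplevels(as.factor(dat[[v]])))
    for (i in seq_along(levs)) {
      if (i == 1) {
        rows[[length(rows) + 1]] <- data.frame(
          outcome = outcome, term = v, level = levs[1], reference = levs[1],
          estimate = if (exponentiate) 1 else 0,
          ci_low = NA_real_, ci_high = NA_real_, se_log = NA_real_,
          stringsAsFactors = FALSE)
      } else {
        nm <- paste0(v, levs[i])
        b <- est[[nm]]
        s <- se[[nm]]
        lo <- b - 1.96 * s
        hi <- b + 1.96 * s
        rows[[length(rows) + 1]] <- data.frame(
          outcome = outcome, term = v, level = levs[i], reference = levs[1],
          estimate = if (exponentiate) exp(b) else b,
          ci_low = if (exponentiate) exp(lo) else lo,
          ci_high = if (exponentiate) exp(hi) else hi,
          se_log = s, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "fit") <- fit
  attr(out, "vcov") <- vcov_mat
  out
}

#' Run the full hospitalisation/readmission/length-of-stay model grid
#'
#' For each multimorbidity subset (MM2, MM3) fits: the weighted Poisson
#' prevalence-ratio model of hospitalisation on sex + age band, and the two
#' within-sex age-band models; then, on the hospitalised members of the
#' subset, the corresponding weighted linear models for readmission count
#' and length of stay. This mirrors the standard reporting layout of such
#' analyses (joint model, then age within each sex).
#'
#' @param table Complete-case cohort table with `combined_weight` and MM
#'   flags (see [fit_ipw_weights()], [classify_mm()]).
#' @return A `data.frame` of stacked results with `subset` and `stratum`
#'   columns (`stratum` is `"all"`, `"female"`, or `"male"`).
#' @export
run_regression_suite <- function(table) {
  if (is.null(table$mm2)) table <- classify_mm(table)
  res <- list()
  for (subset in c("mm2", "mm3")) {
    sub <- table[table[[subset]], , drop = FALSE]
    models <- list(
      all = list(data = sub, covs = c("sex", "age_group")),
      female = list(data = sub[sub$sex == "female", , drop = FALSE],
                    covs = "age_group"),
      male = list(data = sub[sub$sex == "male", , drop = FALSE],
                  covs = "age_group")
    )
    for (stratum in names(models)) {
      m <- models[[stratum]]
      r <- fit_weighted_poisson_pr(m$data, "hospitalised", m$covs)
      r$subset <- subset; r$stratum <- stratum
      res[[length(res) + 1]] <- r
      hosp <- m$data[m$data$hospitalised == 1, , drop = FALSE]
      for (outc in c("readmissions", "length_of_stay")) {
        r <- fit_weighted_linear(hosp, outc, m$covs)
        r$subset <- subset; r$stratum <- stratum
        res[[length(res) + 1]] <- r
      }
    }
  }
  out <- do.call(rbind, lapply(res, function(r) { attributes(r)$fit <- NULL; r }))
  rownames(out) <- NULL
  out[, c("subset", "stratum", "outcome", "term", "level", "reference",
          "estimate", "ci_low", "ci_high", "se_log")]
}
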