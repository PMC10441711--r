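analysis_columns <- function() {
  c(disease_catalog(), "hospitalised", "sex", "age_group", "survey_weight")
}

#' Extract complete cases
#'
#' Removes rows with any missing analysis variable (the 19 disease
#' indicators, hospitalisation, sex, age band, survey weight). Readmission
#' and length of stay are structurally missing for non-hospitalised persons
#' and are therefore not part of the completeness criterion.
#'
#' @param table Cohort `data.frame`.
#' @return Complete-case table; the number of dropped rows is recorded in
#'   the `"n_dropped"` attribute and reported via `message()`.
#' @export
complete_cases <- function(table) {
  keep <- stats::complete.cases(table[, analysis_columns()])
  if (!any(keep)) stop("no complete cases remain after filtering")
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  message(sum(!keep), " incomplete row(s) removed; ", nrow(out), " retained")
  out
}

#' Inverse-probability weights for complete-case analysis
#'
#' Fits, on the full table (complete and incomplete rows), a logistic model
#' of completeness on the always-observed covariates sex and age band; each
#' complete case is then reweighted by `survey_weight / completeness_prob`.
#' The combined weight is normalised to unit mean over complete cases, which
#' leaves all downstream prevalence ratios and regression coefficients
#' unchanged while keeping effective sample sizes honest.
#'
#' @param full_table Cohort table including the incomplete rows.
#' @return The complete-case table augmented with `completeness_prob` and
#'   `combined_weight` columns; the fitted completeness model is attached as
#'   the `"ipw_model"` attribute.
#' @export
fit_ipw_weights <- function(full_table) {
  complete <- stats::complete.cases(full_table[, analysis_columns()])
  strata_complete <- tapply(complete,
                            list(full_table$sex, full_table$age_group), sum)
  if (any(strata_complete == 0, na.rm = TRUE)) {
    bad <- which(strata_complete == 0, arr.ind = TRUE)
    stop("stratum with no complete cases (separation): ",
         paste(rownames(strata_complete)[bad[, 1]],
               colnames(strata_complete)[bad[, 2]], sep = "/",
               collapse = ", "))
  }
  if (all(complete)) {
    # nothing missing: completeness probability is identically 1 and the
    # logistic model would be degenerate
    prob <- rep(1, nrow(full_table))[complete]
    fit <- NULL
  } else {
    dat <- data.frame(complete = as.numeric(complete),
                      sex = full_table$sex, age_group = full_table$age_group)
    fit <- stats::glm(complete ~ sex + age_group, data = dat,
                      family = stats::binomial())
    prob <- stats::fitted(fit)[complete]
  }
  out <- full_table[complete, , drop = FALSE]
  rownames(out) <- NULL
  out$completeness_prob <- as.numeric(prob)
  w <- out$survey_weight / out$completeness_prob
  out$combined_weight <- w / mean(w)
  attr(out, "ipw_model") <- fit
  attr(out, "n_dropped") <- sum(!complete)
  out
}

#' Multimorbidity classification
#'
#' Counts each person's conditions and flags multimorbidity under the two
#' definitions used throughout: MM2 (at least 2 of the 19 conditions) and
#' MM3 (at least 3). MM3 cases are by construction a subset of MM2 cases.
#'
#' @param table Complete-case cohort table.
#' @return The table with `condition_count`, `mm2`, `mm3` columns added.
#' @export
classify_mm <- function(table) {
  X <- as.matrix(table[, disease_catalog()])
  if (anyNA(X)) {
    stop("disease indicators contain missing values; run complete_cases() first")
  }
  table$condition_count <- as.integer(rowSums(X))
  table$mm2 <- table$condition_count >= 2L
  table$mm3 <- table$condition_count >= 3L
  table
}

#' Split a cohort into named strata
#'
#' `sex`, `age_group`, and `sex_age` partition the table exhaustively;
#' `mm2`/`mm3` return the multimorbid subset only (the analysis population
#' of the corresponding regression tables); `network` returns the five
#' marginal strata the network analysis uses (female, male, and the three
#' age bands — note these overlap).
#'
#' @param table Cohort table (with MM columns for the `mm2`/`mm3` keys; see
#'   [classify_mm()]).
#' @param by One of `"sex"`, `"age_group"`, `"sex_age"`, `"mm2"`, `"mm3"`,
#'   `"network"`.
#' @return Named list of sub-tables.
#' @export
stratify <- function(table, by = c("sex", "age_group", "sex_age",
                                   "mm2", "mm3", "network")) {
  by <- match.arg(by)
  drop_rn <- function(x) { rownames(x) <- NULL; x }
  switch(by,
    sex = lapply(split(table, table$sex), drop_rn),
    age_group = lapply(split(table, table$age_group), drop_rn),
    sex_age = lapply(split(table, interaction(table$sex, table$age_group,
                                              sep = ".")), drop_rn),
    mm2 = ,
    mm3 = {
      if (is.null(table[[by]])) stop("run classify_mm() before '", by, "'")
      stats::setNames(list(drop_rn(table[table[[by]], , drop = FALSE])), by)
    },
    network = c(lapply(split(table, table$sex), drop_rn),
                lapply(split(table, table$age_group), drop_rn))
  )
}
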