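#' Generate a synthetic analysis-ready cohort
#'
#' Draws a person-level table from a known ground truth: sex and age band
#' from the stratum mix, disease indicators from the Ising model (with
#' stratum-shifted thresholds, sampled by Gibbs), hospitalisation from a
#' logistic model on the disease indicators, readmission counts (1 + Poisson
#' on the log scale, counting the index admission by default) and gamma
#' length of stay for hospitalised persons, and lognormal survey weights
#' with mean one. Missingness is NOT applied here; see [apply_missingness()].
#'
#' @param truth An [ground_truth()] object.
#' @param n Number of persons.
#' @param stratum_mix Optional override of `truth$stratum_mix`.
#' @param seed Integer seed (restores the caller's RNG state).
#' @param readmission_includes_index If `TRUE` (default) the readmission
#'   count includes the index admission, hence is at least 1 whenever
#'   hospitalised; if `FALSE` it counts only further admissions.
#' @param burn_in,thin Gibbs sampler settings for the disease draws.
#' @return A `data.frame` with columns `id`, `sex`, `age_group`, the 19
#'   disease indicators, `hospitalised`, `readmissions`, `length_of_stay`,
#'   and `survey_weight`. The seed is recorded in the `"seed"` attribute.
#' @export
generate_cohort <- function(truth, n, stratum_mix = NULL, seed = NULL,
                            readmission_includes_index = TRUE,
                            burn_in = 1000, thin = 10) {
  stopifnot(inherits(truth, "mm_ground_truth"))
  if (n <= 0) stop("n must be positive")
  mix <- if (is.null(stratum_mix)) truth$stratum_mix else stratum_mix
  if (any(mix < 0) || !isTRUE(all.equal(sum(mix), 1, tolerance = 1e-8))) {
    stop("stratum_mix must be nonnegative and sum to 1")
  }
  catalog <- disease_catalog()
  out <- with_seed(seed, {
    cell <- sample(names(mix), n, replace = TRUE, prob = mix)
    parts <- strsplit(cell, ".", fixed = TRUE)
    sex <- factor(vapply(parts, `[`, "", 1), levels = sex_levels())
    age <- factor(vapply(parts, `[`, "", 2), levels = age_levels())
    X <- matrix(0L, n, 19, dimnames = list(NULL, catalog))
    for (s in sex_levels()) {
      for (a in age_levels()) {
        idx <- which(sex == s & age == a)
        if (!length(idx)) next
        th <- truth$thresholds + (s == "male") * truth$sex_shift +
          truth$age_shift[, a]
        X[idx, ] <- sample_ising_gibbs(truth$edge_weights, th, length(idx),
                                       burn_in = burn_in, thin = thin)
      }
    }
    male <- as.numeric(sex == "male")
    a50 <- as.numeric(age == "50-59")
    a75 <- as.numeric(age == "75+")
    lp <- function(coefs) {
      eta <- rep(coefs[["intercept"]], n)
      dis <- intersect(names(coefs), catalog)
      if (length(dis)) eta <- eta + X[, dis, drop = FALSE] %*% coefs[dis]
      for (term in c("male", "age_50_59", "age_75plus")) {
        if (term %in% names(coefs)) {
          eta <- eta + coefs[[term]] *
            switch(term, male = male, age_50_59 = a50, age_75plus = a75)
        }
      }
      as.numeric(eta)
    }
    hosp <- stats::rbinom(n, 1, expit(lp(truth$outcome_coeffs$hospitalisation)))
    readm <- rep(NA_integer_, n)
    los <- rep(NA_real_, n)
    hi <- which(hosp == 1)
    if (length(hi)) {
      extra <- stats::rpois(length(hi),
                            exp(lp(truth$outcome_coeffs$readmission))[hi])
      readm[hi] <- extra + as.integer(readmission_includes_index)
      mu <- exp(lp(truth$outcome_coeffs$length_of_stay))[hi]
      los[hi] <- stats::rgamma(length(hi), shape = truth$los_shape,
                               rate = truth$los_shape / mu)
    }
    w <- stats::rlnorm(n, meanlog = -0.125, sdlog = 0.5)
    df <- data.frame(id = seq_len(n), sex = sex, age_group = age,
                     X, hospitalised = hosp, readmissions = readm,
                     length_of_stay = los, survey_weight = w,
                     stringsAsFactors = FALSE)
    df
  })
  attr(out, "seed") <- seed
  out
}

#' Apply a missing-at-random masking model to a cohort
#'
#' Each person's disease/outcome block is set to missing with probability
#' `logistic(model . covariates)`, where the model may depend only on the
#' always-observed covariates sex and age band (the MAR condition). Stratum
#' variables and survey weights are never masked.
#'
#' @param table A cohort `data.frame` from [generate_cohort()].
#' @param missing_model Named coefficients: `intercept` and optionally
#'   `male`, `age_50_59`, `age_75plus`.
#' @param seed Integer seed.
#' @return The table with masked rows set to `NA` in the disease and outcome
#'   columns.
#' @export
apply_missingness <- function(table, missing_model, seed = NULL) {
  allowed <- c("intercept", "male", "age_50_59", "age_75plus")
  bad <- setdiff(names(missing_model), allowed)
  if (length(bad)) {
    stop("missing_model references maskable fields (violates MAR): ",
         paste(bad, collapse = ", "))
  }
  getc <- function(nm) if (nm %in% names(missing_model)) missing_model[[nm]] else 0
  eta <- getc("intercept") +
    getc("male") * (table$sex == "male") +
    getc("age_50_59") * (table$age_group == "50-59") +
    getc("age_75plus") * (table$age_group == "75+")
  mask <- with_seed(seed, stats::rbinom(nrow(table), 1, expit(eta)) == 1)
  cols <- c(disease_catalog(), "hospitalised", "readmissions", "length_of_stay")
  table[mask, cols] <- NA
  table
}

#' Read and write cohort tables as CSV
#'
#' The on-disk dialect is a plain header CSV with empty cells for missing
#' values. Disease indicators and `hospitalised` must be coded 0/1 (the
#' strings `"yes"`/`"no"` are also accepted and recoded); `sex` and
#' `age_group` must use the canonical levels. Unknown columns are preserved.
#'
#' @param path File path.
#' @return `read_cohort_csv()` returns a validated cohort `data.frame`.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  mandatory <- c(disease_catalog(), "hospitalised", "sex", "age_group",
                 "survey_weight")
  miss <- setdiff(mandatory, names(df))
  if (length(miss)) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  recode01 <- function(x, col) {
    if (is.character(x)) {
      x <- tolower(trimws(x))
      x[x == "yes"] <- "1"
      x[x == "no"] <- "0"
      x <- suppressWarnings(as.numeric(x))
    }
    bad <- which(!is.na(x) & !(x %in% c(0, 1)))
    if (length(bad)) {
      stop("non-binary value in column '", col, "' at row ", bad[1])
    }
    as.integer(x)
  }
  for (col in c(disease_catalog(), "hospitalised")) {
    df[[col]] <- recode01(df[[col]], col)
  }
  df$sex <- factor(df$sex, levels = sex_levels())
  df$age_group <- factor(df$age_group, levels = age_levels())
  if (anyNA(df$sex) || anyNA(df$age_group)) {
    stop("sex/age_group contain values outside the canonical levels")
  }
  if (any(!is.na(df$survey_weight) & df$survey_weight <= 0)) {
    stop("survey_weight must be positive")
  }
  df
}

#' @param table Cohort table to write.
#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Serialise a ground truth as JSON
#'
#' Writes couplings, thresholds, shifts, outcome models, community labels,
#' missingness model, stratum mix, and the generating seed (when supplied)
#' so a scenario can be archived next to the cohorts drawn from it.
#'
#' @param truth An [ground_truth()] object.
#' @param path Output path.
#' @param seed Optional seed to record alongside the scenario.
#' @return The path, invisibly.
#' @export
write_ground_truth_json <- function(truth, path, seed = NULL) {
  stopifnot(inherits(truth, "mm_ground_truth"))
  payload <- list(
    diseases = disease_catalog(),
    edge_weights = truth$edge_weights,
    thresholds = as.list(truth$thresholds),
    sex_shift = as.list(truth$sex_shift),
    age_shift = truth$age_shift,
    outcome_coeffs = lapply(truth$outcome_coeffs, as.list),
    community_labels = as.list(truth$community_labels),
    missing_model = as.list(truth$missing_model),
    stratum_mix = as.list(truth$stratum_mix),
    los_shape = truth$los_shape,
    seed = seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
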