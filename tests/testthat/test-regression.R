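two_group_table <- function(n1, e1, n0, e0, w1 = 1, w0 = 1) {
  data.frame(
    grp = factor(rep(c("unexposed", "exposed"), c(n0, n1)),
                 levels = c("unexposed", "exposed")),
    y = c(rep(c(1, 0), c(e0, n0 - e0)), rep(c(1, 0), c(e1, n1 - e1))),
    w = rep(c(w0, w1), c(n0, n1)))
}

test_that("saturated Poisson model returns the exact prevalence ratio", {
  tab <- two_group_table(n1 = 100, e1 = 20, n0 = 100, e0 = 10)
  res <- fit_weighted_poisson_pr(tab, "y", "grp", weights = tab$w)
  pr <- res$estimate[res$level == "exposed"]
  expect_equal(pr, 2.0, tolerance = 1e-8)
  expect_equal(res$estimate[res$level == "unexposed"], 1)
})

test_that("weighted saturated model reproduces weighted group prevalence ratios", {
  set.seed(41)
  n <- 300
  tab <- data.frame(grp = factor(sample(c("a", "b"), n, TRUE)),
                    y = rbinom(n, 1, 0.3),
                    w = runif(n, 0.2, 3))
  res <- fit_weighted_poisson_pr(tab, "y", "grp", weights = tab$w)
  pa <- weighted.mean(tab$y[tab$grp == "a"], tab$w[tab$grp == "a"])
  pb <- weighted.mean(tab$y[tab$grp == "b"], tab$w[tab$grp == "b"])
  expect_equal(res$estimate[res$level == "b"], pb / pa, tolerance = 1e-7)
})

test_that("sandwich variance matches a direct score-based computation", {
  set.seed(43)
  n <- 40
  tab <- data.frame(grp = factor(sample(c("a", "b", "c"), n, TRUE)),
                    y = rbinom(n, 1, 0.4),
                    w = runif(n, 0.5, 2))
  res <- fit_weighted_poisson_pr(tab, "y", "grp", weights = tab$w)
  # direct sandwich: B = sum w mu x x', M = sum (w (y - mu) x)^2 outer
  X <- model.matrix(~grp, tab)
  fit <- attr(res, "fit")
  eta <- X %*% coef(fit)
  mu <- exp(eta)
  B <- crossprod(X, X * as.numeric(tab$w * mu))
  S <- X * as.numeric(tab$w * (tab$y - mu))
  M <- crossprod(S)
  V <- solve(B) %*% M %*% solve(B)
  expect_equal(attr(res, "vcov"), V, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("recoding the reference level inverts the prevalence ratio", {
  tab <- two_group_table(80, 24, 120, 18)
  r1 <- fit_weighted_poisson_pr(tab, "y", "grp")
  tab2 <- tab
  tab2$grp <- stats::relevel(tab2$grp, "exposed")
  r2 <- fit_weighted_poisson_pr(tab2, "y", "grp")
  expect_equal(r1$estimate[r1$level == "exposed"],
               1 / r2$estimate[r2$level == "unexposed"], tolerance = 1e-8)
})

test_that("robust Poisson CI has near-nominal null coverage", {
  # null two-group design: PR = 1; coverage of the 95% sandwich CI
  set.seed(47)
  hits <- replicate(400, {
    tab <- data.frame(grp = factor(rep(c("a", "b"), each = 150)),
                      y = rbinom(300, 1, 0.25),
                      w = runif(300, 0.5, 2))
    res <- fit_weighted_poisson_pr(tab, "y", "grp", weights = tab$w)
    row <- res[res$level == "b", ]
    row$ci_low <= 1 && 1 <= row$ci_high
  })
  expect_gt(mean(hits), 0.91)
  expect_lt(mean(hits), 0.99)
})

test_that("single-level covariates are dropped with a warning", {
  tab <- two_group_table(50, 10, 50, 10)
  tab$sex <- factor("female", levels = c("female", "male"))
  expect_warning(res <- fit_weighted_poisson_pr(tab, "y", c("grp", "sex")),
                 "sex")
  expect_false("sex" %in% res$term)
  tab$grp <- factor("exposed")
  expect_error(suppressWarnings(
    fit_weighted_poisson_pr(tab, "y", c("grp", "sex"))), "covariate")
})

test_that("weighted linear model recovers a planted sex effect on length of stay", {
  # generator scenario where the male effect is the only determinant of
  # length of stay: female mean 5 days, male mean 8 days (+3.0)
  truth <- elsi_like_truth()
  truth$outcome_coeffs$length_of_stay[] <- 0
  truth$outcome_coeffs$length_of_stay[["intercept"]] <- log(5)
  truth$outcome_coeffs$length_of_stay[["male"]] <- log(8 / 5)
  truth$outcome_coeffs$hospitalisation[] <- 0
  truth$outcome_coeffs$hospitalisation[["intercept"]] <- qlogis(0.35)
  coh <- generate_cohort(truth, 15000, seed = 51, burn_in = 200, thin = 2)
  hosp <- coh[coh$hospitalised == 1, ]
  res <- fit_weighted_linear(hosp, "length_of_stay", "sex",
                             weights = hosp$survey_weight)
  row <- res[res$level == "male", ]
  expect_lt(abs(row$estimate - 3.0), 2 * row$se_log)
})

test_that("weighted linear fits honour WLS invariances and degeneracies", {
  set.seed(53)
  tab <- data.frame(grp = factor(sample(c("a", "b"), 60, TRUE)),
                    y = rnorm(60, 5), w = runif(60, 0.5, 2))
  r1 <- fit_weighted_linear(tab, "y", "grp", weights = tab$w)
  # duplicated rows at halved weight leave the estimate unchanged
  tab2 <- rbind(tab, tab)
  tab2$w <- tab2$w / 2
  r2 <- fit_weighted_linear(tab2, "y", "grp", weights = tab2$w)
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-10)
  # constant outcome: zero effects with zero-width intervals (the perfect
  # fit makes summary machinery grumble, which is immaterial here)
  tab$y <- 3
  r3 <- suppressWarnings(fit_weighted_linear(tab, "y", "grp",
                                             weights = tab$w))
  row <- r3[r3$level == "b", ]
  expect_equal(row$estimate, 0, tolerance = 1e-12)
  expect_equal(row$ci_high - row$ci_low, 0, tolerance = 1e-10)
})

test_that("the regression suite covers the full subset x stratum x outcome grid", {
  cc <- classify_mm(fit_ipw_weights(quick_cohort(4000, seed = 55)))
  suite <- run_regression_suite(cc)
  expect_setequal(unique(suite$subset), c("mm2", "mm3"))
  expect_setequal(unique(suite$stratum), c("all", "female", "male"))
  expect_setequal(unique(suite$outcome),
                  c("hospitalised", "readmissions", "length_of_stay"))
  grid <- unique(suite[, c("subset", "stratum", "outcome")])
  expect_equal(nrow(grid), 2 * 3 * 3)
  # PRs positive, CIs ordered
  est <- suite[!is.na(suite$ci_low), ]
  expect_true(all(est$ci_low <= est$estimate & est$estimate <= est$ci_high))
  expect_true(all(suite$estimate[suite$outcome == "hospitalised"] > 0))
})
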