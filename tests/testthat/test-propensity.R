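test_that("intercept-only fit recovers the closed-form MLE", {
  Z <- rep(c(1, 0), c(23, 980))
  fit <- fit_logistic(matrix(numeric(0), 1003, 0), Z)
  expect_equal(unname(fit$coefficients[1]), qlogis(23 / 1003), tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("degenerate exposure vectors are rejected", {
  expect_error(fit_logistic(matrix(0, 10, 0), rep(0, 10)), "no exposed")
  expect_error(fit_logistic(matrix(0, 10, 0), rep(1, 10)), "no unexposed")
})

test_that("saturated single-covariate fit equals the sample log odds ratio", {
  # x = 0 stratum: 10 exposed / 90 unexposed; x = 1 stratum: 40 / 60
  x <- rep(c(0, 1), c(100, 100))
  Z <- c(rep(c(1, 0), c(10, 90)), rep(c(1, 0), c(40, 60)))
  fit <- fit_logistic(matrix(x, dimnames = list(NULL, "x")), Z)
  expect_equal(unname(fit$coefficients["x"]), log(6), tolerance = 1e-8)
  # fitted probabilities are exactly the cell proportions
  expect_equal(sort(unique(round(fit$fitted_ps, 10))), c(0.1, 0.4))
})

test_that("separation and singularity are reported by name", {
  x <- c(rep(1, 20), rep(0, 80))
  Z <- c(rep(1, 20), rep(0, 80)) # x predicts exposure perfectly
  expect_error(fit_logistic(matrix(x, dimnames = list(NULL, "leaky")), Z),
               "leaky")
  X2 <- cbind(a = c(x[1:99], 0), b = c(x[1:99], 0)) # duplicated column
  Z2 <- rbinom(100, 1, 0.3)
  set.seed(4); Z2 <- rbinom(100, 1, 0.3)
  expect_error(fit_logistic(X2, Z2), "singular")
})

test_that("ATE weights follow the inverse-probability definition", {
  expect_equal(ate_weights(rep(0.5, 4), c(1, 1, 0, 0)), rep(2, 4))
  w <- ate_weights(rep(23 / 1003, 3), c(1, 1, 1))
  expect_equal(w, rep(1003 / 23, 3))
  expect_error(ate_weights(c(0, 0.5), c(0, 1)), "strictly")

  # pseudo-population identity: each weighted arm totals about n
  coh <- add_iptw(generate_cohort(confounded_config(4000, seed = 21)))
  n <- nrow(coh)
  expect_lt(abs(sum(coh$iptw_weight[coh$exposure == 1]) - n) / n, 0.15)
  expect_lt(abs(sum(coh$iptw_weight[coh$exposure == 0]) - n) / n, 0.15)
})

test_that("c-statistic equals the brute-force pairwise probability", {
  expect_equal(c_statistic(c(0.9, 0.4, 0.8, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(c_statistic(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(c_statistic(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(c_statistic(runif(5), rep(1, 5)), "both")

  brute <- function(ps, Z) {
    e <- ps[Z == 1]; u <- ps[Z == 0]
    mean(outer(e, u, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(88)
  for (i in 1:10) {
    n <- sample(10:200, 1)
    ps <- sample(seq(0, 1, 0.05), n, replace = TRUE) # plenty of ties
    Z <- rbinom(n, 1, 0.4)
    if (sum(Z) %in% c(0, n)) next
    expect_equal(c_statistic(ps, Z), brute(ps, Z), tolerance = 1e-12)
  }
})

test_that("weighting improves covariate balance on confounded data", {
  coh <- add_iptw(generate_cohort(confounded_config(5000, seed = 31)))
  raw <- covariate_balance(coh)
  wtd <- covariate_balance(coh, w = coh$iptw_weight)
  expect_lt(abs(wtd$smd[wtd$covariate == "confounder"]),
            abs(raw$smd[raw$covariate == "confounder"]))
  expect_lt(max(abs(wtd$smd)), max(abs(raw$smd)))
})

test_that("add_iptw validates covariate availability", {
  coh <- generate_cohort(confounded_config(300, seed = 2))
  expect_error(add_iptw(coh, covariates = c("confounder", "ghost")), "ghost")
})
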