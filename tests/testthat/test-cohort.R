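test_that("exposure assignment matches the configured marginal model", {
  # no covariate effects: pure Bernoulli(0.5) exposure
  cfg <- cohort_config(n = 10000, exposure_intercept = qlogis(0.5),
                       outcome_intercept = log(0.01),
                       exposure_effect_rd = 0, covariates = list(),
                       seed = 101)
  coh <- generate_cohort(cfg)
  expect_lt(abs(mean(coh$exposure) - 0.5), 3 * sqrt(0.25 / 10000))

  # calibrated default: exposed count near 23 out of 1003
  coh2 <- suppressWarnings(generate_cohort(cohort_config(n = 1003, seed = 42)))
  sd_bin <- sqrt(1003 * 0.023 * 0.977)
  expect_lt(abs(sum(coh2$exposure) - 23), 3 * sd_bin)
})

test_that("null effect makes the potential outcomes identical", {
  cfg <- cohort_config(n = 10000, exposure_effect_rd = 0,
                       covariates = list(), exposure_prevalence = 0.3,
                       outcome_baseline = 0.05, seed = 7)
  coh <- generate_cohort(cfg)
  expect_identical(coh$y0, coh$y1) # monotone coupling with zero shift
  expect_equal(mean(coh$y1) - mean(coh$y0), 0)
})

test_that("the generated cohort realises the configured causal effect", {
  cfg <- confounded_config(50000, seed = 9)
  coh <- generate_cohort(cfg)
  ate <- mean(coh$y1 - coh$y0)
  mc_se <- sd(coh$y1 - coh$y0) / sqrt(nrow(coh))
  expect_lt(abs(ate - 0.07), 3 * mc_se)
})

test_that("covariate marginals are calibrated", {
  coh <- suppressWarnings(generate_cohort(cohort_config(n = 20000, seed = 3)))
  for (cv in default_covariates()) {
    p <- cv$prevalence
    expect_lt(abs(mean(coh[[cv$name]]) - p), 3 * sqrt(p * (1 - p) / 20000),
              label = cv$name)
  }
})

test_that("identical config and seed give byte-identical CSV output", {
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(generate_cohort(confounded_config(500, seed = 11)), f1)
  write_cohort(generate_cohort(confounded_config(500, seed = 11)), f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed does not
  f3 <- tempfile(fileext = ".csv")
  write_cohort(generate_cohort(confounded_config(500, seed = 12)), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(covariate_spec("x", 1.2), "prevalence")
  expect_error(covariate_spec("x", 0.5, beta_outcome = Inf), "finite")
  # a risk-raising pattern pushing p beyond 1 names the covariates involved
  expect_error(
    cohort_config(n = 100, covariates = list(
      covariate_spec("huge_risk", 0.5, beta_outcome = log(400))),
      outcome_intercept = log(0.01), seed = 1),
    "huge_risk")
  expect_error(cohort_config(n = 0), "n")
})

test_that("rare-event configurations warn rather than fail", {
  expect_warning(generate_cohort(cohort_config(n = 200, seed = 5)),
                 "unstable")
})

test_that("published cross-tabulation fixture has the documented margins", {
  t <- abruption_two_by_two()
  expect_equal(t$a + t$b, 23)   # exposed column total
  expect_equal(t$c + t$d, 980)  # unexposed column total
  expect_equal(t$a + t$b + t$c + t$d, 1003)
  expect_equal(t$a + t$c, 9)    # abruption cases
})

test_that("2x2 expansion round-trips exactly", {
  t <- abruption_two_by_two()
  coh <- expand_two_by_two(t)
  expect_equal(nrow(coh), 1003)
  expect_equal(sum(coh$exposure), 23)
  expect_equal(sum(coh$outcome), 9)
  rt <- tabulate_cohort(coh)
  expect_equal(unclass(rt)[c("a", "b", "c", "d")],
               unclass(t)[c("a", "b", "c", "d")])

  empty <- expand_two_by_two(two_by_two(0, 5, 0, 5))
  expect_equal(nrow(empty), 10)
  expect_equal(sum(empty$outcome), 0)
})

test_that("cohort validation enforces the data contract", {
  bad <- tibble::tibble(exposure = c(0, 2), outcome = c(0, 1))
  expect_error(validate_cohort(bad), "0/1")
  bad2 <- tibble::tibble(exposure = c(0, 1), outcome = c(NA, 1))
  expect_error(validate_cohort(bad2), "missing")
})
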