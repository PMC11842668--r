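test_that("crude contrasts from the published counts match hand arithmetic", {
  est <- crude_effects(abruption_two_by_two())
  expect_equal(est$rd$point, 2 / 23 - 7 / 980, tolerance = 1e-12)
  expect_equal(round(est$rd$point, 2), 0.08)
  expect_equal(est$rr$point, (2 / 23) / (7 / 980), tolerance = 1e-12)

  sym <- crude_effects(two_by_two(5, 5, 5, 5))
  expect_equal(sym$rd$point, 0)
  expect_equal(sym$rr$point, 1)
})

test_that("risk-ratio degeneracies are handled as documented", {
  expect_warning(out <- crude_effects(two_by_two(3, 7, 0, 10)), "unexposed")
  expect_null(out$rr)
  expect_s3_class(out$rd, "effect_estimate") # RD still returned
  expect_error(suppressWarnings(weighted_rr_modified_poisson(
    c(0, 0, 1, 0), c(1, 1, 0, 0))), "case")
})

test_that("GLM routes reproduce saturated closed forms with unit weights", {
  tabs <- c(list(abruption_two_by_two()), lapply(1:8, random_two_by_two))
  for (t in tabs) {
    coh <- expand_two_by_two(t)
    cf <- closed_form_2x2(t)
    rd <- weighted_rd_glm(coh$outcome, coh$exposure)
    rr <- weighted_rr_modified_poisson(coh$outcome, coh$exposure)
    expect_equal(rd$point, cf$rd, tolerance = 1e-8)
    expect_equal(rd$se, cf$rd_se, tolerance = 1e-8)
    expect_equal(rr$point, cf$rr, tolerance = 1e-8)
    expect_equal(rr$se, cf$log_rr_se, tolerance = 1e-8)
  }
})

test_that("constant propensity weights cancel within arms", {
  coh <- expand_two_by_two(abruption_two_by_two())
  ps <- rep(mean(coh$exposure), nrow(coh)) # intercept-only propensity
  w <- ate_weights(ps, coh$exposure)
  rd <- weighted_rd_glm(coh$outcome, coh$exposure, w)
  expect_equal(rd$point, 2 / 23 - 7 / 980, tolerance = 1e-12)
})

test_that("equal arm rates give a null effect", {
  Y <- rep(c(1, 0, 1, 0), c(3, 27, 3, 27))
  Z <- rep(c(1, 0), c(30, 30))
  expect_equal(weighted_rr_modified_poisson(Y, Z)$point, 1, tolerance = 1e-10)
  expect_equal(weighted_rd_glm(Y, Z)$point, 0, tolerance = 1e-12)
})

test_that("confidence bounds are coherent across levels and scales", {
  coh <- expand_two_by_two(abruption_two_by_two())
  lv <- c(0.80, 0.90, 0.95, 0.99)
  rrs <- lapply(lv, function(l)
    weighted_rr_modified_poisson(coh$outcome, coh$exposure, ci_level = l))
  lows <- vapply(rrs, `[[`, numeric(1), "ci_low")
  highs <- vapply(rrs, `[[`, numeric(1), "ci_high")
  expect_true(all(diff(lows) < 0))  # wider level, lower bound decreases
  expect_true(all(diff(highs) > 0))
  expect_true(all(lows > 0))        # exponentiated bounds stay positive
  for (r in rrs) expect_true(r$ci_low <= r$point && r$point <= r$ci_high)
})

test_that("IPTW corrects the confounding the crude estimator shows", {
  # single deterministic large cohort; potential outcomes give the truth
  coh <- generate_cohort(confounded_config(40000, seed = 17))
  truth <- mean(coh$y1 - coh$y0)
  crude <- crude_effects(tabulate_cohort(coh))$rd$point
  coh <- add_iptw(coh)
  iptw <- weighted_rd_glm(coh$outcome, coh$exposure, coh$iptw_weight)$point
  expect_lt(abs(iptw - truth), 0.01)
  expect_gt(abs(crude - truth), abs(iptw - truth))
  expect_gt(crude - truth, 0.01) # the built-in upward bias
})

test_that("tidy() rows carry the full estimate contract", {
  td <- tidy(crude_effects(abruption_two_by_two())$rr)
  expect_named(td, c("scale", "estimate", "std.error", "conf.low",
                     "conf.high", "conf.level", "n", "cases", "method"))
  expect_equal(td$n, 1003)
  expect_equal(td$cases, 9)
})
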