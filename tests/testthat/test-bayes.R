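test_that("the HMC sampler recovers a known Gaussian target", {
  # independent N(0, 1) and N(5, 4): lp and gradient in closed form
  lp_grad <- function(th) list(
    lp = -0.5 * th[1]^2 - 0.5 * (th[2] - 5)^2 / 4,
    grad = c(-th[1], -(th[2] - 5) / 4))
  d1 <- hmc_chain(lp_grad, c(0, 5), n_warmup = 500, n_draws = 1500, seed = 1)
  d2 <- hmc_chain(lp_grad, c(1, 3), n_warmup = 500, n_draws = 1500, seed = 2)
  all_d <- rbind(d1, d2)
  expect_lt(abs(mean(all_d[, 1]) - 0), 0.12)
  expect_lt(abs(mean(all_d[, 2]) - 5), 0.25)
  expect_lt(abs(var(all_d[, 1]) - 1), 0.25)
  expect_lt(abs(var(all_d[, 2]) - 4), 1.0)
  expect_lte(split_r_hat(list(d1[, 1], d2[, 1])), 1.02)
})

test_that("posterior concentrates at the MLE when the data dominate", {
  set.seed(20)
  Z <- rbinom(3000, 1, 0.5)
  post <- sample_ps_posterior(matrix(numeric(0), length(Z), 0), Z,
                              chains = 2, draws = 400, warmup = 400, seed = 5)
  pm <- mean(plogis(do.call(rbind, post$chains)[, 1]))
  expect_lt(abs(pm - mean(Z)), 0.02)

  # Bernstein-von-Mises check against the IRLS fit with covariates
  set.seed(21)
  X <- cbind(u = rbinom(2000, 1, 0.3), v = rbinom(2000, 1, 0.5))
  Z2 <- rbinom(2000, 1, plogis(-1.5 + 0.7 * X[, 1] + 0.7 * X[, 2]))
  mle <- fit_logistic(X, Z2)$coefficients
  post2 <- sample_ps_posterior(X, Z2, chains = 2, draws = 600, warmup = 600,
                               seed = 6)
  draws <- do.call(rbind, post2$chains)
  for (j in seq_along(mle))
    expect_lt(abs(mean(draws[, j]) - mle[j]), 0.5 * sd(draws[, j]))
})

test_that("sampling is deterministic given the seed and needs >= 2 chains", {
  set.seed(30)
  X <- matrix(rbinom(400, 1, 0.4), ncol = 1, dimnames = list(NULL, "x"))
  Z <- rbinom(400, 1, plogis(-1 + X[, 1]))
  a <- sample_ps_posterior(X, Z, chains = 2, draws = 100, warmup = 100, seed = 9)
  b <- sample_ps_posterior(X, Z, chains = 2, draws = 100, warmup = 100, seed = 9)
  expect_identical(a$chains, b$chains)
  expect_error(sample_ps_posterior(X, Z, chains = 1, draws = 50, warmup = 50),
               "chains")
})

test_that("split-Rhat separates mixed from unmixed chains", {
  set.seed(40)
  x <- rnorm(1000)
  expect_lt(abs(split_r_hat(list(x, x)) - 1), 0.01) # exact copies
  expect_gt(split_r_hat(list(rnorm(500, 0), rnorm(500, 10))), 1.5)
  expect_error(split_r_hat(list(rep(1, 100), rep(1, 100))), "constant")
  expect_error(split_r_hat(list(rnorm(100))), "2 chains")
})

test_that("HDI matches distributional oracles", {
  set.seed(50)
  h <- hdi_interval(rnorm(10000), 0.94)
  expect_lt(abs(h[["low"]] + 1.881), 0.1) # z at 3% tails
  expect_lt(abs(h[["high"]] - 1.881), 0.1)

  hu <- hdi_interval(runif(10000), 0.94)
  expect_lt(abs((hu[["high"]] - hu[["low"]]) - 0.94), 0.02)

  he <- hdi_interval(rep(2.5, 25), 0.94)
  expect_equal(unname(he[["high"]] - he[["low"]]), 0)

  x <- rnorm(500)
  hh <- hdi_interval(x, 0.5)
  expect_gte(hh[["low"]], min(x)); expect_lte(hh[["high"]], max(x))
  expect_error(hdi_interval(rnorm(100), 1.2), "mass")
  expect_error(hdi_interval(rnorm(5)), "20")
})

test_that("constant propensity draws reproduce the crude risk difference", {
  coh <- expand_two_by_two(abruption_two_by_two())
  # degenerate posterior: every draw is the intercept-only MLE
  b0 <- qlogis(mean(coh$exposure))
  draws <- matrix(b0, nrow = 50, ncol = 1)
  eff <- iptw_effect_draws(coh$outcome, coh$exposure,
                           matrix(numeric(0), nrow(coh), 0), draws)
  expect_equal(unique(round(eff$rd, 12)), round(2 / 23 - 7 / 980, 12))
  expect_equal(unique(round(eff$rr, 9)), round((2 / 23) / (7 / 980), 9))
})

test_that("closed-form per-draw effects equal the GLM route", {
  coh <- generate_cohort(confounded_config(800, seed = 61))
  X <- as.matrix(coh[cohort_covariates(coh)])
  set.seed(62)
  draws <- cbind(rnorm(5, -2, 0.3), rnorm(5, 1, 0.3), rnorm(5, 0.5, 0.3))
  eff <- iptw_effect_draws(coh$outcome, coh$exposure, X, draws)
  for (m in 1:5) {
    ps <- plogis(cbind(1, X) %*% draws[m, ])
    w <- ate_weights(pmin(pmax(ps, 1e-6), 1 - 1e-6), coh$exposure)
    expect_equal(eff$rd[m],
                 weighted_rd_glm(coh$outcome, coh$exposure, w)$point,
                 tolerance = 1e-10)
    expect_equal(eff$rr[m],
                 weighted_rr_modified_poisson(coh$outcome, coh$exposure,
                                              w)$point,
                 tolerance = 1e-8)
  }
})

test_that("a posterior pinned at the frequentist fit matches frequentist IPTW", {
  coh <- generate_cohort(confounded_config(1500, seed = 63))
  coh <- add_iptw(coh)
  mle <- attr(coh, "ps_fit")$coefficients
  freq_rd <- weighted_rd_glm(coh$outcome, coh$exposure, coh$iptw_weight)$point
  # sampler stub honouring the contract: chains of the MLE point
  pin <- function(lp_grad, init, n_warmup, n_draws, seed, ...) {
    m <- matrix(rep(c(mle[1], qlogis((mle[-1] + 10) / 20)), each = n_draws),
                nrow = n_draws)
    m + 1e-9 * matrix(rnorm(length(m)), nrow = n_draws) # non-constant chains
  }
  fit <- two_step_bayes_ate(coh, chains = 2, draws = 100, warmup = 10,
                            seed = 1, sampler = pin)
  expect_equal(fit$rd$mean, freq_rd, tolerance = 1e-4)
})

test_that("the two-step posterior recovers the generator truth", {
  coh <- generate_cohort(cohort_config(n = 1000, seed = 42))
  fit <- two_step_bayes_ate(coh, chains = 2, draws = 500, warmup = 500,
                            seed = 77)
  expect_lt(abs(fit$rd$mean - 0.07), 3 * fit$rd$sd)
  expect_true(fit$rd$hdi_low <= fit$rd$mean && fit$rd$mean <= fit$rd$hdi_high)
  # HDI lies inside the sample range
  expect_gte(fit$rd$hdi_low, min(fit$effect_draws$rd))
  expect_lte(fit$rd$hdi_high, max(fit$effect_draws$rd))
  td <- tidy(fit)
  expect_equal(td$scale, c("RD", "RR"))
  expect_equal(glance(fit)$draws, 1000)
})

test_that("two-step preconditions are enforced", {
  coh <- expand_two_by_two(two_by_two(0, 23, 7, 973))
  expect_error(two_step_bayes_ate(coh, chains = 2, draws = 50, warmup = 50),
               "case")
})
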