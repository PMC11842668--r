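# Shared fixtures, built in code.

# Two-covariate generator with deliberately strong confounding: the
# confounder quadruples the exposure odds and triples the baseline risk, so
# the crude risk difference is biased upward by about +0.019 while the true
# causal risk difference is 0.07.
confounded_config <- function(n, seed) {
  cohort_config(
    n = n, exposure_effect_rd = 0.07,
    covariates = list(
      covariate_spec("confounder", 0.3, beta_exposure = log(4),
                     beta_outcome = log(3)),
      covariate_spec("risk_prone", 0.2, beta_exposure = log(2))
    ),
    exposure_prevalence = 0.10, outcome_baseline = 0.05, seed = seed
  )
}

# Random non-degenerate 2x2 tables for saturated-model oracle checks.
random_two_by_two <- function(seed) {
  with_seed <- function(s, e) { set.seed(s); e }
  with_seed(seed, {
    two_by_two(sample(1:30, 1), sample(1:300, 1),
               sample(1:30, 1), sample(1:300, 1))
  })
}

# Closed-form saturated-model estimates and HC0 sandwich SEs for a 2x2.
closed_form_2x2 <- function(t) {
  n1 <- t$a + t$b; n0 <- t$c + t$d
  p1 <- t$a / n1; p0 <- t$c / n0
  list(rd = p1 - p0,
       rd_se = sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0),
       rr = p1 / p0,
       log_rr_se = sqrt((1 - p1) / (n1 * p1) + (1 - p0) / (n0 * p0)))
}
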