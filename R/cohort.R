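#' Specify a binary baseline covariate
#'
#' Describes one binary covariate of the synthetic cohort: its marginal
#' prevalence, its log-odds effect on the exposure (propensity model) and its
#' log-risk effect on the baseline outcome rate. Covariates with nonzero
#' effects on both scales act as confounders.
#'
#' @param name covariate label (unique within a config).
#' @param prevalence marginal prevalence, strictly inside (0, 1).
#' @param beta_exposure log-odds effect on exposure; 0 for no effect.
#' @param beta_outcome log-risk effect on the untreated outcome rate.
#' @return a `covariate_spec` list.
#' @export
#' @examples
#' covariate_spec("partner_htp", 163 / 1003, beta_exposure = log(7))
covariate_spec <- function(name, prevalence, beta_exposure = 0, beta_outcome = 0) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1)
    abort(paste0("prevalence of `", name, "` must lie strictly in (0, 1)"))
  if (!all(is.finite(c(beta_exposure, beta_outcome))))
    abort(paste0("effects of `", name, "` must be finite"))
  structure(
    list(name = name, prevalence = prevalence,
         beta_exposure = beta_exposure, beta_outcome = beta_outcome),
    class = "covariate_spec"
  )
}

#' Default covariate set emulating the motivating pregnancy cohort
#'
#' Sixteen binary baseline covariates whose marginal prevalences match the
#' published characteristics table of the internet-survey cohort of 1003
#' pregnancies that motivates this package (maternal age extremes, parity,
#' in-vitro fertilization, alcohol use, hypertensive and metabolic disorders,
#' previous abruption, membrane/placental complications, fetal sex, and own
#' and partner tobacco use). A handful carry nonzero effects sized from the
#' cross-tabulated odds ratios in that table, so the default cohort is
#' confounded: own traditional-tobacco smoking, partner smoking and IVF raise
#' the odds of heated-tobacco-product use, while previous abruption,
#' hypertensive disorders, placenta previa and tobacco exposure raise the
#' baseline abruption risk.
#'
#' @return list of [covariate_spec()] objects.
#' @export
default_covariates <- function() {
  n <- 1003
  list(
    covariate_spec("age_extreme",     264 / n),
    covariate_spec("parity_ge3",       29 / n),
    covariate_spec("ivf",              17 / n, beta_exposure = log(10)),
    covariate_spec("alcohol",          38 / n),
    covariate_spec("chronic_htn",       6 / n),
    covariate_spec("pregest_dm",        5 / n),
    covariate_spec("thyroid_dysf",     37 / n),
    covariate_spec("prev_abruption",    2 / n, beta_outcome = log(6)),
    covariate_spec("hdp",              59 / n, beta_outcome = log(2.5)),
    covariate_spec("prom",             91 / n),
    covariate_spec("placenta_previa",  27 / n, beta_outcome = log(2)),
    covariate_spec("sga_fetus",        70 / n),
    covariate_spec("male_fetus",      507 / n),
    covariate_spec("trad_smoking",     17 / n, beta_exposure = log(10),
                   beta_outcome = log(2)),
    covariate_spec("partner_trad",    133 / n, beta_exposure = log(3.5)),
    covariate_spec("partner_htp",     163 / n, beta_exposure = log(7),
                   beta_outcome = log(1.5))
  )
}

# E[exp(X g)] for independent Bernoulli covariates (closed form).
mgf_bernoulli <- function(prev, g) prod(1 - prev + prev * exp(g))

# E[expit(a + X b)] by exact enumeration over the covariates with b != 0.
expected_exposure_prev <- function(a, prev, b) {
  nz <- which(b != 0)
  if (length(nz) == 0) return(expit(a))
  patt <- as.matrix(expand.grid(rep(list(0:1), length(nz))))
  pr <- apply(patt, 1, function(x) prod(ifelse(x == 1, prev[nz], 1 - prev[nz])))
  sum(pr * expit(a + drop(patt %*% b[nz])))
}

#' Configure a synthetic cohort generator
#'
#' Builds a validated generation config. Intercepts may be given directly on
#' the model scale, or (default) calibrated so the marginal exposure
#' prevalence and the mean untreated outcome risk hit stated targets under
#' independent covariates: the outcome intercept has a closed form via the
#' Bernoulli moment generating function; the exposure intercept is solved
#' numerically by exact enumeration over the covariates with nonzero
#' exposure effects.
#'
#' The outcome follows an excess-risk model: untreated risk
#' `p0(x) = exp(outcome_intercept + x * beta_outcome)` and treated risk
#' `p0(x) + exposure_effect_rd`, so `exposure_effect_rd` is the true
#' causal risk difference for every covariate pattern (and hence the ATE).
#' Construction fails, naming the offending covariate pattern, if any
#' pattern's implied risk leaves \[0, 1\].
#'
#' @param n cohort size (>= 1).
#' @param exposure_effect_rd true causal risk difference of exposure on
#'   outcome; defaults to 0.07.
#' @param covariates list of [covariate_spec()]; defaults to
#'   [default_covariates()].
#' @param exposure_prevalence target marginal exposure prevalence used to
#'   calibrate the exposure intercept (ignored when `exposure_intercept`
#'   is supplied). Default 0.023, i.e. 23/1003.
#' @param outcome_baseline target mean untreated outcome risk (ignored when
#'   `outcome_intercept` supplied). Default 0.007.
#' @param exposure_intercept,outcome_intercept optional intercepts on the
#'   log-odds / log-risk scale, overriding calibration.
#' @param seed integer root seed; per-stage streams are derived from it.
#' @return a `cohort_config` list.
#' @export
#' @examples
#' cfg <- cohort_config(n = 1003, seed = 42)
#' cfg$exposure_intercept
cohort_config <- function(n = 1003,
                          exposure_effect_rd = 0.07,
                          covariates = default_covariates(),
                          exposure_prevalence = 0.023,
                          outcome_baseline = 0.007,
                          exposure_intercept = NULL,
                          outcome_intercept = NULL,
                          seed = 42) {
  if (!is.numeric(n) || n < 1) abort("`n` must be >= 1")
  stopifnot(all(vapply(covariates, inherits, logical(1), "covariate_spec")))
  nm <- vapply(covariates, `[[`, character(1), "name")
  if (anyDuplicated(nm)) abort("covariate names must be unique")
  prev <- vapply(covariates, `[[`, numeric(1), "prevalence")
  b_z <- vapply(covariates, `[[`, numeric(1), "beta_exposure")
  b_y <- vapply(covariates, `[[`, numeric(1), "beta_outcome")

  if (is.null(exposure_intercept)) {
    stopifnot(exposure_prevalence > 0, exposure_prevalence < 1)
    exposure_intercept <- stats::uniroot(
      function(a) expected_exposure_prev(a, prev, b_z) - exposure_prevalence,
      lower = -30, upper = 30, tol = 1e-12
    )$root
  }
  if (is.null(outcome_intercept)) {
    stopifnot(outcome_baseline > 0, outcome_baseline < 1)
    outcome_intercept <- log(outcome_baseline) - log(mgf_bernoulli(prev, b_y))
  }

  # worst-case covariate pattern on the risk scale
  hi <- b_y > 0
  p0_max <- exp(outcome_intercept + sum(b_y[hi]))
  p0_min <- exp(outcome_intercept + sum(b_y[b_y < 0]))
  if (p0_max + max(exposure_effect_rd, 0) > 1)
    abort(paste0(
      "implied outcome probability exceeds 1 for covariate pattern {",
      paste(nm[hi], collapse = ", "), " = 1}"
    ))
  if (p0_min + min(exposure_effect_rd, 0) < 0)
    abort(paste0(
      "implied outcome probability below 0 for covariate pattern {",
      paste(nm[b_y < 0], collapse = ", "), " = 1}"
    ))

  structure(
    list(n = as.integer(n),
         exposure_intercept = exposure_intercept,
         outcome_intercept = outcome_intercept,
         exposure_effect_rd = exposure_effect_rd,
         covariates = covariates,
         covariate_names = nm,
         prevalence = setNames(prev, nm),
         beta_exposure = setNames(b_z, nm),
         beta_outcome = setNames(b_y, nm),
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Generate a synthetic cohort with known potential outcomes
#'
#' Draws independent binary covariates at their configured prevalences,
#' assigns exposure from the logistic model
#' `logit P(Z = 1 | x) = exposure_intercept + x * beta_exposure`, and draws
#' potential outcomes by monotone coupling: one uniform `u` per subject with
#' `y0 = u < p0(x)` and `y1 = u < p0(x) + exposure_effect_rd`, so
#' `y1 >= y0` subject-wise whenever the effect is harmful and the true ATE
#' equals the configured risk difference by construction. The observed
#' outcome is the potential outcome under the assigned exposure.
#'
#' A warning (not an error) is issued when the expected number of cases
#' falls below 5 — risk estimates are unstable in that regime.
#'
#' @param config a [cohort_config()].
#' @return a tibble of class `cohort_tbl` with columns `id`, `exposure`,
#'   `outcome`, one 0/1 column per covariate, and synthetic-truth columns
#'   `y0`, `y1`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n = 500, seed = 1))
#' mean(coh$y1 - coh$y0) # true effect realised in this cohort
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  seeds <- derive_seeds(config$seed, 3L)
  n <- config$n
  p <- length(config$covariates)

  X <- with_seed(seeds[1], {
    matrix(rbinom(n * p, 1, rep(config$prevalence, each = n)), nrow = n,
           dimnames = list(NULL, config$covariate_names))
  })

  lin_z <- rep(config$exposure_intercept, n) +
    if (p > 0) drop(X %*% config$beta_exposure) else 0
  Z <- with_seed(seeds[2], rbinom(n, 1, expit(lin_z)))

  p0 <- exp(rep(config$outcome_intercept, n) +
              if (p > 0) drop(X %*% config$beta_outcome) else 0)
  p1 <- pmin(pmax(p0 + config$exposure_effect_rd, 0), 1)
  u <- with_seed(seeds[3], runif(n))
  Y0 <- as.integer(u < p0)
  Y1 <- as.integer(u < p1)
  Y <- ifelse(Z == 1, Y1, Y0)

  exp_cases <- sum(expit(lin_z) * p1 + (1 - expit(lin_z)) * p0)
  if (exp_cases < 5)
    warn(sprintf("expected case count %.1f < 5; risk estimates may be unstable",
                 exp_cases))

  out <- tibble(id = seq_len(n), exposure = as.integer(Z),
                outcome = as.integer(Y))
  out <- dplyr::bind_cols(out, as_tibble(X))
  out$y0 <- Y0
  out$y1 <- Y1
  new_cohort_tbl(out, covariate_names = config$covariate_names)
}

new_cohort_tbl <- function(x, covariate_names = character()) {
  structure(x, class = c("cohort_tbl", class(tibble())),
            covariates = covariate_names)
}

#' Names of the covariate columns of a cohort table
#' @param cohort a cohort tibble.
#' @return character vector of covariate column names.
#' @export
cohort_covariates <- function(cohort) {
  cv <- attr(cohort, "covariates")
  if (!is.null(cv)) return(cv)
  setdiff(names(cohort), c("id", "exposure", "outcome", "y0", "y1",
                           "ps", "iptw_weight"))
}

#' Validate a cohort table
#'
#' Checks the contract every estimation function assumes: 0/1 exposure and
#' outcome, no missing values anywhere, unique column names.
#'
#' @param cohort data frame with `exposure` and `outcome` columns.
#' @return the cohort, invisibly, as a tibble.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  if (anyDuplicated(names(cohort))) abort("column names must be unique")
  if (!all(c("exposure", "outcome") %in% names(cohort)))
    abort("cohort must have `exposure` and `outcome` columns")
  check_binary(cohort$exposure, "exposure")
  check_binary(cohort$outcome, "outcome")
  if (anyNA(cohort)) abort("cohort contains missing values")
  invisible(as_tibble(cohort))
}
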