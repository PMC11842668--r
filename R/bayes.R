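#' Priors for the Bayesian propensity-score model
#'
#' The propensity intercept gets a heavy-tailed Cauchy prior centred at the
#' logit of an assumed population exposure prevalence (default 12.6%, the
#' assumed population rate of heated-tobacco-product use) with scale 2.5;
#' every covariate coefficient gets an uninformative uniform prior on
#' (-10, 10) on the log-odds scale. The analogous Cauchy anchor for the
#' outcome prevalence (default 0.7%) is carried for documentation and
#' reporting — the per-draw outcome step of the two-step procedure is a
#' weighted frequentist fit, so no outcome prior enters the likelihood.
#'
#' @param exposure_prevalence assumed population exposure prevalence.
#' @param outcome_prevalence assumed population outcome prevalence
#'   (documentation anchor only).
#' @param intercept_scale Cauchy scale for the intercept prior, default 2.5.
#' @param coef_lower,coef_upper uniform prior bounds for coefficients.
#' @return a `prior_spec` list.
#' @export
prior_spec <- function(exposure_prevalence = 0.126,
                       outcome_prevalence = 0.007,
                       intercept_scale = 2.5,
                       coef_lower = -10, coef_upper = 10) {
  stopifnot(coef_lower < coef_upper, intercept_scale > 0,
            exposure_prevalence > 0, exposure_prevalence < 1,
            outcome_prevalence > 0, outcome_prevalence < 1)
  structure(
    list(intercept_location = logit(exposure_prevalence),
         intercept_scale = intercept_scale,
         outcome_anchor = logit(outcome_prevalence),
         coef_lower = coef_lower, coef_upper = coef_upper),
    class = "prior_spec"
  )
}

# Joint log-posterior and gradient of the logistic PS model in an
# unconstrained parameterisation: the intercept is free (Cauchy prior);
# each bounded coefficient beta = lower + range * plogis(u) with the
# log-Jacobian folded in, so Hamiltonian trajectories never hit a hard
# boundary.
make_ps_logpost <- function(X, Z, priors) {
  Xd <- cbind(`(Intercept)` = 1, as.matrix(X))
  p <- ncol(Xd)
  lo <- priors$coef_lower; rg <- priors$coef_upper - priors$coef_lower
  loc <- priors$intercept_location; sc <- priors$intercept_scale

  to_beta <- function(theta) {
    if (p == 1) return(theta)
    c(theta[1], lo + rg * expit(theta[-1]))
  }
  lp_grad <- function(theta) {
    beta <- to_beta(theta)
    eta <- drop(Xd %*% beta)
    mu <- expit(eta)
    ll <- sum(Z * eta - log1p(exp(eta)))
    dl_dbeta <- drop(crossprod(Xd, Z - mu))
    # Cauchy prior on intercept
    ia <- beta[1] - loc
    lp <- ll - log1p((ia / sc)^2)
    g <- dl_dbeta
    g[1] <- g[1] - 2 * ia / (ia^2 + sc^2)
    if (p > 1) {
      s <- expit(theta[-1])
      # Jacobian of the bounded transform + its own gradient
      lp <- lp + sum(log(s) + log(1 - s)) # + const p*log(rg)
      g[-1] <- g[-1] * rg * s * (1 - s) + (1 - 2 * s)
    }
    list(lp = lp, grad = g)
  }
  list(lp_grad = lp_grad, to_beta = to_beta, param_names = colnames(Xd))
}

#' Sample the posterior of the logistic propensity-score model
#'
#' Runs several independent MCMC chains (adaptive Hamiltonian Monte Carlo
#' by default, see [hmc_chain()]) on the logistic exposure model under
#' [prior_spec()] priors, and returns post-warmup coefficient draws on the
#' natural log-odds scale together with split-Rhat diagnostics.
#'
#' @param X covariate matrix / data frame (zero columns for intercept-only).
#' @param Z 0/1 exposure vector.
#' @param priors a [prior_spec()].
#' @param chains number of chains, at least 2 (split-Rhat is undefined for
#'   a single chain). Default 4.
#' @param draws post-warmup draws per chain; default 2500, for 10,000 total
#'   draws with 4 chains.
#' @param warmup adaptation iterations per chain, default 1000.
#' @param seed root seed; chain seeds are derived from it.
#' @param sampler sampler function with the contract of [hmc_chain()].
#' @return a `ps_posterior`: per-chain draw matrices, parameter names,
#'   per-parameter split-Rhat, acceptance rates.
#' @export
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(n = 400, seed = 9))
#' post <- sample_ps_posterior(coh[cohort_covariates(coh)], coh$exposure,
#'                             chains = 2, draws = 300, warmup = 300, seed = 1)
#' max(post$r_hat)
#' }
sample_ps_posterior <- function(X, Z, priors = prior_spec(), chains = 4,
                                draws = 2500, warmup = 1000, seed = 1,
                                sampler = hmc_chain) {
  Z <- check_binary(Z, "Z")
  if (chains < 2) abort("at least 2 chains are required (split-Rhat undefined)")
  X <- as.matrix(X)
  if (nrow(X) == 0) X <- matrix(numeric(0), length(Z), 0)
  mod <- make_ps_logpost(X, Z, priors)
  d <- length(mod$param_names)
  seeds <- derive_seeds(seed, chains + 1L)

  init_theta <- function(cs) with_seed(cs, {
    c(logit(clip01(mean(Z))) + rnorm(1, 0, 0.5), rnorm(d - 1, 0, 0.5))
  })
  chain_list <- lapply(seq_len(chains), function(ch) {
    raw <- sampler(mod$lp_grad, init_theta(seeds[ch]), n_warmup = warmup,
                   n_draws = draws, seed = seeds[ch])
    beta <- t(apply(raw, 1, mod$to_beta))
    if (d == 1) beta <- matrix(as.numeric(raw), ncol = 1)
    colnames(beta) <- mod$param_names
    attr(beta, "accept_rate") <- attr(raw, "accept_rate")
    attr(beta, "divergences") <- attr(raw, "divergences")
    beta
  })
  r_hat <- vapply(seq_len(d), function(j) {
    split_r_hat(lapply(chain_list, function(m) m[, j]))
  }, numeric(1))
  structure(
    list(chains = chain_list, param_names = mod$param_names,
         n_chains = chains, draws_per_chain = draws, warmup = warmup,
         r_hat = setNames(r_hat, mod$param_names),
         accept_rate = vapply(chain_list, function(m)
           attr(m, "accept_rate") %||% NA_real_, numeric(1)),
         divergences = vapply(chain_list, function(m)
           attr(m, "divergences") %||% NA_real_, numeric(1)),
         priors = priors, seed = seed),
    class = "ps_posterior"
  )
}

#' @export
print.ps_posterior <- function(x, ...) {
  cat(sprintf("propensity posterior: %d chains x %d draws, %d parameters\n",
              x$n_chains, x$draws_per_chain, length(x$param_names)))
  cat(sprintf("max split-Rhat %.4f; mean acceptance %.2f\n",
              max(x$r_hat), mean(x$accept_rate)))
  invisible(x)
}

#' Split-Rhat convergence diagnostic
#'
#' Splits each chain in half, then compares between- and within-half-chain
#' variances: with `m` draws per half-chain, `B` the variance of half-chain
#' means times `m` and `W` the mean within-half-chain variance, the
#' statistic is `sqrt((W (m - 1)/m + B/m) / W)`. Values near 1 indicate
#' mixing; the conventional gate is 1.01.
#'
#' @param chains list of numeric vectors, one per chain (at least 2 chains
#'   of at least 4 draws each).
#' @return the split-Rhat statistic.
#' @export
split_r_hat <- function(chains) {
  if (!is.list(chains) || length(chains) < 2) abort("need at least 2 chains")
  if (any(lengths(chains) < 4)) abort("need at least 4 draws per chain")
  halves <- unlist(lapply(chains, function(x) {
    n <- length(x) %/% 2
    list(x[seq_len(n)], x[seq_len(n) + (length(x) - n)])
  }), recursive = FALSE)
  m <- min(lengths(halves))
  halves <- lapply(halves, function(x) x[seq_len(m)])
  W <- mean(vapply(halves, var, numeric(1)))
  if (W == 0) abort("zero within-chain variance (constant chain)")
  B <- m * var(vapply(halves, mean, numeric(1)))
  sqrt((W * (m - 1) / m + B / m) / W)
}

#' Highest-density interval of a sample
#'
#' The narrowest contiguous interval containing `ceiling(mass * n)` of the
#' sorted draws — for unimodal posteriors, the highest-density interval.
#'
#' @param samples numeric draws (at least 20).
#' @param mass interval probability mass in (0, 1); default 0.94.
#' @return named vector `c(low, high)`.
#' @export
hdi_interval <- function(samples, mass = 0.94) {
  if (mass <= 0 || mass >= 1) abort("`mass` must lie in (0, 1)")
  x <- sort(samples[is.finite(samples)])
  n <- length(x)
  if (n < 20) abort("need at least 20 samples for an HDI")
  k <- ceiling(mass * n)
  i <- seq_len(n - k + 1)
  width <- x[i + k - 1] - x[i]
  j <- which.min(width)
  c(low = x[j], high = x[j + k - 1])
}

#' Per-draw IPTW effect estimates
#'
#' For each posterior coefficient draw, computes propensity scores for every
#' row, ATE weights, and the weighted risk difference and risk ratio. For an
#' outcome model with only an intercept and the exposure indicator these are
#' the closed-form weighted arm-mean contrasts, identical to the
#' identity-Gaussian GLM slope and exponentiated modified-Poisson slope.
#'
#' @param Y,Z 0/1 outcome and exposure vectors.
#' @param X covariate matrix matching the draw columns (without intercept).
#' @param beta_draws draws matrix, one row per draw, intercept first.
#' @param clip_eps propensity clipping bound.
#' @param chunk draws are processed in blocks of this size to bound memory.
#' @return tibble with one row per draw: `rd`, `rr`.
#' @export
iptw_effect_draws <- function(Y, Z, X, beta_draws, clip_eps = 1e-6,
                              chunk = 500L) {
  Y <- check_binary(Y, "Y"); Z <- check_binary(Z, "Z")
  Xd <- cbind(1, as.matrix(X))
  stopifnot(ncol(Xd) == ncol(beta_draws))
  n_draws <- nrow(beta_draws)
  rd <- rr <- numeric(n_draws)
  y1 <- Y * Z; y0 <- Y * (1 - Z)
  for (start in seq(1, n_draws, by = chunk)) {
    idx <- start:min(start + chunk - 1, n_draws)
    ps <- clip01(expit(Xd %*% t(beta_draws[idx, , drop = FALSE])), clip_eps)
    w1 <- Z / ps            # n x m, zero on unexposed rows
    w0 <- (1 - Z) / (1 - ps)
    m1 <- colSums(w1 * Y) / colSums(w1)
    m0 <- colSums(w0 * Y) / colSums(w0)
    rd[idx] <- m1 - m0
    rr[idx] <- m1 / m0
  }
  tibble(rd = rd, rr = rr)
}

summarise_effect_draws <- function(x, mass) {
  h <- hdi_interval(x, mass)
  list(mean = mean(x), hdi_low = h[["low"]], hdi_high = h[["high"]],
       sd = sd(x), mass = mass)
}

#' Two-step Bayesian IPTW sensitivity analysis
#'
#' The sensitivity analysis for unstable rare-event weighting: first sample
#' the posterior of the logistic propensity model ([sample_ps_posterior()]);
#' then, for every posterior draw, form ATE weights and fit the weighted
#' outcome contrasts (risk difference and risk ratio); finally average the
#' per-draw estimates into a posterior for each effect, reported as the
#' posterior mean with a 94% highest-density interval, alongside the
#' maximum split-Rhat across propensity parameters.
#'
#' Draws whose weighted fit is degenerate (non-finite effect) are dropped
#' with a count; more than 1% dropped draws is an error.
#'
#' @param cohort cohort tibble with `exposure`, `outcome` and covariates.
#' @param covariates covariate columns for the propensity model.
#' @param priors a [prior_spec()].
#' @param chains,draws,warmup,seed,sampler passed to [sample_ps_posterior()].
#' @param hdi_mass HDI mass, default 0.94.
#' @param clip_eps propensity clipping bound.
#' @return a `bayes_iptw` object; `tidy()` gives one row per effect scale.
#' @export
two_step_bayes_ate <- function(cohort, covariates = cohort_covariates(cohort),
                               priors = prior_spec(), chains = 4,
                               draws = 2500, warmup = 1000, seed = 1,
                               hdi_mass = 0.94, clip_eps = 1e-6,
                               sampler = hmc_chain) {
  validate_cohort(cohort)
  Y <- cohort$outcome; Z <- cohort$exposure
  if (length(unique(Z)) < 2) abort("both exposure arms must be present")
  if (sum(Y[Z == 1]) < 1 || sum(Y[Z == 0]) < 1)
    abort("at least one case per arm is required")
  X <- as.matrix(cohort[covariates])
  post <- sample_ps_posterior(X, Z, priors, chains = chains, draws = draws,
                              warmup = warmup, seed = seed, sampler = sampler)
  beta_all <- do.call(rbind, post$chains)
  eff <- iptw_effect_draws(Y, Z, X, beta_all, clip_eps)
  ok <- is.finite(eff$rd) & is.finite(eff$rr)
  dropped <- sum(!ok)
  if (dropped > 0.01 * nrow(eff))
    abort(sprintf("%d of %d posterior draws gave degenerate weighted fits",
                  dropped, nrow(eff)))
  eff <- eff[ok, ]
  structure(
    list(rd = summarise_effect_draws(eff$rd, hdi_mass),
         rr = summarise_effect_draws(eff$rr, hdi_mass),
         effect_draws = eff,
         posterior = post,
         r_hat_max = max(post$r_hat),
         dropped_draws = dropped),
    class = "bayes_iptw"
  )
}

#' @export
print.bayes_iptw <- function(x, ...) {
  cat(sprintf(
    "Bayesian IPTW (two-step), %d chains x %d draws, max split-Rhat %.4f\n",
    x$posterior$n_chains, x$posterior$draws_per_chain, x$r_hat_max))
  cat(sprintf("  aRD %.4f (%g%% HDI %.4f, %.4f)\n", x$rd$mean,
              100 * x$rd$mass, x$rd$hdi_low, x$rd$hdi_high))
  cat(sprintf("  rRR %.2f (%g%% HDI %.2f, %.2f)\n", x$rr$mean,
              100 * x$rr$mass, x$rr$hdi_low, x$rr$hdi_high))
  if (x$dropped_draws > 0)
    cat(sprintf("  (%d degenerate draws dropped)\n", x$dropped_draws))
  invisible(x)
}

#' @rdname two_step_bayes_ate
#' @param x a `bayes_iptw` object.
#' @param ... unused.
#' @method tidy bayes_iptw
#' @export
tidy.bayes_iptw <- function(x, ...) {
  tibble(scale = c("RD", "RR"),
         estimate = c(x$rd$mean, x$rr$mean),
         hdi_low = c(x$rd$hdi_low, x$rr$hdi_low),
         hdi_high = c(x$rd$hdi_high, x$rr$hdi_high),
         hdi_mass = c(x$rd$mass, x$rr$mass))
}

#' @rdname two_step_bayes_ate
#' @method glance bayes_iptw
#' @export
glance.bayes_iptw <- function(x, ...) {
  tibble(chains = x$posterior$n_chains,
         draws = x$posterior$n_chains * x$posterior$draws_per_chain,
         warmup = x$posterior$warmup,
         r_hat_max = x$r_hat_max,
         dropped_draws = x$dropped_draws,
         mean_accept = mean(x$posterior$accept_rate))
}
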