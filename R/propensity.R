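#' Fit a logistic propensity-score model
#'
#' Maximum-likelihood logistic regression of the exposure on the covariate
#' matrix, fitted by iteratively reweighted least squares, with explicit
#' guards for the degeneracies a rare-exposure cohort can produce: an
#' all-one-class exposure vector, a singular design, and (quasi-)complete
#' separation, flagged when any coefficient escapes beyond 15 on the logit
#' scale and reported with the name of the separating covariate.
#'
#' @param X numeric matrix (or data frame) of covariates; may have zero
#'   columns for an intercept-only model.
#' @param Z 0/1 exposure vector.
#' @param clip_eps fitted probabilities are clipped to
#'   `[clip_eps, 1 - clip_eps]` before weighting; default `1e-6`.
#' @return a `ps_fit` with `coefficients`, `fitted_ps`, `converged`,
#'   `iterations`, and the underlying `glm` object.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n = 1003, seed = 7))
#' # with ~23 exposed, restrict the model to the exposure-relevant covariates:
#' # very rare covariates have no exposed carriers and separate the MLE
#' fit <- fit_logistic(coh[c("ivf", "trad_smoking", "partner_trad",
#'                           "partner_htp")], coh$exposure)
#' glance(fit)
fit_logistic <- function(X, Z, clip_eps = 1e-6) {
  Z <- check_binary(Z, "Z")
  X <- as.matrix(X)
  if (nrow(X) == 0) X <- matrix(numeric(0), length(Z), 0)
  if (anyNA(X)) abort("covariates contain missing values")
  if (all(Z == 0)) abort("no exposed rows: logistic MLE diverges")
  if (all(Z == 1)) abort("no unexposed rows: logistic MLE diverges")
  if (length(Z) < ncol(X) + 1) abort("fewer rows than parameters")
  if (ncol(X) > 0 && is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))

  dat <- data.frame(Z = Z, X, check.names = FALSE)
  form <- if (ncol(X) == 0) Z ~ 1 else
    stats::reformulate(sprintf("`%s`", colnames(X)), response = "Z")
  fit <- withCallingHandlers(
    glm(form, family = binomial(), data = dat,
        control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) invokeRestart("muffleWarning")
  )
  beta <- coef(fit)
  if (anyNA(beta)) {
    bad <- names(beta)[is.na(beta)]
    abort(paste0("singular design: coefficient(s) not estimable for ",
                 paste(bad, collapse = ", ")))
  }
  big <- abs(beta) > 15
  if (any(big[-1]))
    abort(paste0("separation detected: |coefficient| > 15 for covariate(s) ",
                 paste(names(beta)[-1][big[-1]], collapse = ", ")))
  if (big[1])
    abort("separation detected: intercept beyond +/-15 on the logit scale")

  structure(
    list(coefficients = beta,
         fitted_ps = clip01(as.numeric(fitted(fit)), clip_eps),
         converged = fit$converged,
         iterations = fit$iter,
         clip_eps = clip_eps,
         glm = fit),
    class = "ps_fit"
  )
}

#' @export
print.ps_fit <- function(x, ...) {
  cat(sprintf("propensity model: %d coefficients, %s in %d IRLS iterations\n",
              length(x$coefficients),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @rdname fit_logistic
#' @param x a `ps_fit`.
#' @param ... unused.
#' @method tidy ps_fit
#' @export
tidy.ps_fit <- function(x, ...) {
  s <- summary(x$glm)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @rdname fit_logistic
#' @method glance ps_fit
#' @export
glance.ps_fit <- function(x, ...) {
  tibble(n = length(x$fitted_ps), n_terms = length(x$coefficients),
         converged = x$converged, iterations = x$iterations,
         c_statistic = c_statistic(x$fitted_ps, x$glm$y))
}

#' ATE inverse probability of treatment weights
#'
#' Weights each exposed row by the inverse of its propensity score and each
#' unexposed row by the inverse of one minus it, so that each arm is
#' reweighted to the covariate distribution of the whole cohort and the
#' weighted contrast targets the average treatment effect.
#'
#' @param ps propensity scores strictly inside (0, 1).
#' @param Z 0/1 exposure vector.
#' @return positive weight vector.
#' @export
ate_weights <- function(ps, Z) {
  Z <- check_binary(Z, "Z")
  if (any(!is.finite(ps)) || any(ps <= 0) || any(ps >= 1))
    abort("propensity scores must lie strictly in (0, 1)")
  ifelse(Z == 1, 1 / ps, 1 / (1 - ps))
}

#' Concordance statistic of a propensity score
#'
#' Probability that a randomly chosen exposed row has a higher score than a
#' randomly chosen unexposed row, with ties counted one half — the
#' rank-based area under the ROC curve, computed via the Wilcoxon rank sum.
#'
#' @param ps numeric scores.
#' @param Z 0/1 exposure vector with both classes present.
#' @return value in \[0, 1\].
#' @export
c_statistic <- function(ps, Z) {
  Z <- check_binary(Z, "Z")
  n1 <- sum(Z == 1); n0 <- sum(Z == 0)
  if (n1 == 0 || n0 == 0) abort("both exposure classes are required")
  r <- rank(ps) # midranks handle ties as 1/2
  (sum(r[Z == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Attach propensity scores and IPTW weights to a cohort
#'
#' Convenience pipeline step: fits the propensity model on the given
#' covariates and adds `ps` and `iptw_weight` columns.
#'
#' @param cohort cohort tibble.
#' @param covariates character vector of covariate column names; defaults to
#'   every covariate column present.
#' @param clip_eps see [fit_logistic()].
#' @return the cohort with `ps` and `iptw_weight` columns; the `ps_fit` is
#'   attached as attribute `ps_fit`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n = 1003, seed = 7)) |>
#'   add_iptw(covariates = c("ivf", "trad_smoking", "partner_trad",
#'                           "partner_htp"))
#' summary(coh$iptw_weight)
add_iptw <- function(cohort, covariates = cohort_covariates(cohort),
                     clip_eps = 1e-6) {
  validate_cohort(cohort)
  missing_cov <- setdiff(covariates, names(cohort))
  if (length(missing_cov) > 0)
    abort(paste0("covariate column(s) not in cohort: ",
                 paste(missing_cov, collapse = ", ")))
  fit <- fit_logistic(cohort[covariates], cohort$exposure, clip_eps = clip_eps)
  cohort$ps <- fit$fitted_ps
  cohort$iptw_weight <- ate_weights(cohort$ps, cohort$exposure)
  attr(cohort, "ps_fit") <- fit
  cohort
}

#' Weighted standardized mean differences between exposure arms
#'
#' Balance diagnostic: for each covariate, the difference of (weighted) arm
#' means divided by the unweighted pooled standard deviation. Values near 0
#' indicate balance; IPTW should shrink these relative to unit weights.
#'
#' @param cohort cohort tibble.
#' @param covariates covariate columns to assess.
#' @param w weights (default unit weights).
#' @return tibble with `covariate` and `smd`.
#' @export
covariate_balance <- function(cohort, covariates = cohort_covariates(cohort),
                              w = rep(1, nrow(cohort))) {
  validate_cohort(cohort)
  z <- cohort$exposure
  purrr::map_dfr(covariates, function(v) {
    x <- cohort[[v]]
    m1 <- sum(w * x * z) / sum(w * z)
    m0 <- sum(w * x * (1 - z)) / sum(w * (1 - z))
    s <- sqrt((var(x[z == 1]) + var(x[z == 0])) / 2)
    tibble(covariate = v, smd = if (s > 0) (m1 - m0) / s else 0)
  })
}
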