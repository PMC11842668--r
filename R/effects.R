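new_effect_estimate <- function(scale, point, se, ci_level, n, cases,
                                method) {
  z <- z_crit(ci_level)
  if (scale == "RD") {
    ci <- point + c(-1, 1) * z * se
  } else {
    ci <- exp(log(point) + c(-1, 1) * z * se) # se on the log scale
  }
  structure(
    list(scale = scale, point = point, se = se, ci_level = ci_level,
         ci_low = ci[1], ci_high = ci[2], n = n, cases = cases,
         method = method),
    class = "effect_estimate"
  )
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s = %.4f (%g%% CI %.4f, %.4f), robust SE %.4f [%s]\n",
              if (x$scale == "RD") "risk difference" else "risk ratio",
              x$point, 100 * x$ci_level, x$ci_low, x$ci_high, x$se, x$method))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an effect estimate
#' @param x an `effect_estimate`.
#' @param ... unused.
#' @return one-row tibble with scale, estimate, robust SE and Wald CI.
#' @method tidy effect_estimate
#' @export
tidy.effect_estimate <- function(x, ...) {
  tibble(scale = x$scale, estimate = x$point, std.error = x$se,
         conf.low = x$ci_low, conf.high = x$ci_high,
         conf.level = x$ci_level, n = x$n, cases = x$cases,
         method = x$method)
}

#' Crude risk difference and risk ratio from a 2x2 table
#'
#' Unadjusted absolute risk difference `a/(a+b) - c/(c+d)` and relative risk
#' ratio `[a/(a+b)] / [c/(c+d)]`, with the saturated-model sandwich standard
#' errors: `sqrt(p1 q1/n1 + p0 q0/n0)` for the RD and
#' `sqrt((1-p1)/(n1 p1) + (1-p0)/(n0 p0))` for the log RR, and Wald
#' confidence intervals.
#'
#' @param t a [two_by_two()].
#' @param ci_level confidence level, default 0.95.
#' @return list with elements `rd` and `rr` (each an `effect_estimate`);
#'   `rr` is `NULL`, with a warning, when there are no unexposed cases.
#' @export
#' @examples
#' est <- crude_effects(abruption_two_by_two())
#' tidy(est$rd)
crude_effects <- function(t, ci_level = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  n1 <- t$a + t$b; n0 <- t$c + t$d
  p1 <- t$a / n1;  p0 <- t$c / n0
  n <- n1 + n0; cases <- t$a + t$c

  rd_se <- sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0)
  rd <- new_effect_estimate("RD", p1 - p0, rd_se, ci_level, n, cases, "crude")

  if (t$c < 1) {
    warn("no unexposed cases: crude risk ratio undefined, returning RD only")
    return(list(rd = rd, rr = NULL))
  }
  if (t$a < 1) abort("no exposed cases: crude log risk ratio diverges")
  rr_se <- sqrt((1 - p1) / (n1 * p1) + (1 - p0) / (n0 * p0))
  rr <- new_effect_estimate("RR", p1 / p0, rr_se, ci_level, n, cases, "crude")
  list(rd = rd, rr = rr)
}

robust_se <- function(fit) {
  # HC0 sandwich: bread from the weighted information, meat from raw
  # weighted score outer products, no small-sample adjustment.
  v <- sandwich::sandwich(fit)
  sqrt(diag(v))
}

check_two_arms <- function(Y, Z, need_cases = FALSE) {
  if (length(unique(Z)) < 2) abort("both exposure arms must be present")
  if (need_cases && (sum(Y[Z == 1]) < 1 || sum(Y[Z == 0]) < 1))
    abort("at least one case is required in each arm (log-link MLE diverges)")
}

#' IPTW risk difference via identity-link Gaussian GLM
#'
#' Weighted least squares of the outcome on the exposure indicator; the
#' slope is the (weighted) absolute risk difference. The variance is the
#' heteroskedasticity-robust sandwich treating the weights as fixed, i.e.
#' ignoring propensity-estimation uncertainty (the Bayesian two-step
#' addresses that component).
#'
#' @param Y,Z 0/1 outcome and exposure vectors.
#' @param w positive weights (IPTW weights, or unit weights for a crude fit).
#' @param ci_level confidence level, default 0.95.
#' @return an `effect_estimate` on the RD scale.
#' @export
weighted_rd_glm <- function(Y, Z, w = rep(1, length(Y)), ci_level = 0.95) {
  Y <- check_binary(Y, "Y"); Z <- check_binary(Z, "Z")
  if (any(!is.finite(w)) || any(w <= 0)) abort("weights must be positive and finite")
  check_two_arms(Y, Z)
  dat <- data.frame(Y = Y, Z = Z, w = w)
  fit <- glm(Y ~ Z, family = gaussian(), weights = w, data = dat,
             control = stats::glm.control(epsilon = 1e-12))
  se <- robust_se(fit)[["Z"]]
  new_effect_estimate("RD", coef(fit)[["Z"]], se, ci_level,
                      length(Y), sum(Y), "iptw_glm_identity")
}

#' IPTW risk ratio via modified Poisson regression
#'
#' Weighted log-link Poisson GLM of the binary outcome on the exposure
#' indicator; the exponentiated slope is the (weighted) relative risk
#' ratio. Robust sandwich variance on the log scale, Wald CI exponentiated.
#' Fitted as a quasi-Poisson model (identical coefficients; the estimated
#' dispersion cancels in the sandwich product) so non-integer weighted
#' outcomes do not trip the Poisson likelihood check.
#'
#' @inheritParams weighted_rd_glm
#' @return an `effect_estimate` on the RR scale (`se` on the log scale).
#' @export
weighted_rr_modified_poisson <- function(Y, Z, w = rep(1, length(Y)),
                                         ci_level = 0.95) {
  Y <- check_binary(Y, "Y"); Z <- check_binary(Z, "Z")
  if (any(!is.finite(w)) || any(w <= 0)) abort("weights must be positive and finite")
  check_two_arms(Y, Z, need_cases = TRUE)
  dat <- data.frame(Y = Y, Z = Z, w = w)
  fit <- glm(Y ~ Z, family = quasipoisson(link = "log"), weights = w,
             data = dat, control = stats::glm.control(epsilon = 1e-12))
  se <- robust_se(fit)[["Z"]]
  new_effect_estimate("RR", exp(coef(fit)[["Z"]]), se, ci_level,
                      length(Y), sum(Y), "iptw_modified_poisson")
}
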