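#' Bounding factor for joint unmeasured confounding
#'
#' The maximum factor by which an unmeasured confounder with risk-ratio
#' association `rr_ue` with the exposure and `rr_ud` with the outcome
#' (both on the harmful side, i.e. at least 1) can attenuate an observed
#' risk ratio:
#' `B = rr_ud * rr_ue / (rr_ud + rr_ue - 1)`.
#'
#' @param rr_ud confounder-outcome risk ratio, >= 1.
#' @param rr_ue confounder-exposure risk ratio, >= 1. Vectorised.
#' @return the bounding factor `B >= 1`; `B = 1` whenever either input is 1.
#' @export
#' @examples
#' bounding_factor(2, 2)   # 4/3
#' bounding_factor(14, 14) # 196/27
bounding_factor <- function(rr_ud, rr_ue) {
  if (any(rr_ud < 1) || any(rr_ue < 1))
    abort("bounding factor requires rr_ud >= 1 and rr_ue >= 1")
  rr_ud * rr_ue / (rr_ud + rr_ue - 1)
}

#' Attenuate an observed risk ratio by a bounding factor
#'
#' @param rr_pre observed (pre-adjustment) risk ratio, > 0.
#' @param b bounding factor, >= 1.
#' @return the adjusted risk ratio `rr_pre / b`.
#' @export
adjusted_rr <- function(rr_pre, b) {
  if (any(rr_pre <= 0)) abort("`rr_pre` must be positive")
  if (any(b < 1)) abort("bounding factor must be >= 1")
  rr_pre / b
}

#' Minimum joint confounder strength to explain away a risk ratio
#'
#' The E-value: the smallest `x >= 1` such that a confounder with
#' `rr_ue = rr_ud = x` has bounding factor at least `rr`, i.e. can move the
#' observed association all the way to the null. Closed form: the positive
#' root of `x^2 - 2 rr x + rr = 0`, `x = rr + sqrt(rr (rr - 1))`.
#'
#' @param rr observed risk ratio (or its confidence bound nearer the null),
#'   >= 1.
#' @return the minimum joint strength.
#' @export
#' @examples
#' min_joint_strength(7.5)  # 14.48: nullifying the lower confidence bound
#' min_joint_strength(11.3) # 22.09: nullifying the point estimate
min_joint_strength <- function(rr) {
  if (any(rr < 1)) abort("`rr` must be >= 1")
  rr + sqrt(rr * (rr - 1))
}

#' Bias grid over joint confounder strengths
#'
#' Evaluates the post-adjustment risk ratio on a lattice of
#' confounder-exposure and confounder-outcome risk ratios, by default
#' spanning 1 (no association) to 15 (strong association) in steps of 0.5.
#'
#' @param rr_pre observed risk ratio to be attenuated.
#' @param axis_max upper end of both axes, default 15.
#' @param step lattice step, default 0.5.
#' @return a tibble of class `bias_grid` with columns
#'   `rr_ue`, `rr_ud`, `b`, `rr_post`; `rr_pre` is kept as an attribute.
#' @export
#' @examples
#' g <- bias_grid(11.3)
#' dplyr::filter(g, rr_ue == 15, rr_ud == 15)
bias_grid <- function(rr_pre, axis_max = 15, step = 0.5) {
  if (rr_pre <= 0) abort("`rr_pre` must be positive")
  ax <- seq(1, axis_max, by = step)
  g <- tidyr::expand_grid(rr_ue = ax, rr_ud = ax) |>
    dplyr::mutate(b = bounding_factor(.data$rr_ud, .data$rr_ue),
                  rr_post = adjusted_rr(rr_pre, .data$b))
  structure(g, class = c("bias_grid", class(g)), rr_pre = rr_pre)
}

#' Summarise a multiple-bias analysis
#'
#' Reports, for the observed risk ratio and optionally the confidence bound
#' nearer the null, the minimum joint confounder strength that would
#' nullify each. The published claim of interest is usually the bound:
#' moving the lower confidence limit to 1 refutes the whole interval.
#'
#' @param rr_pre observed risk ratio.
#' @param ci_null_bound optional confidence bound nearer the null.
#' @return tibble with `quantity`, `rr`, `min_joint_strength`.
#' @export
bias_summary <- function(rr_pre, ci_null_bound = NULL) {
  out <- tibble(quantity = "point", rr = rr_pre,
                min_joint_strength = min_joint_strength(rr_pre))
  if (!is.null(ci_null_bound))
    out <- dplyr::bind_rows(out, tibble(
      quantity = "ci_bound", rr = ci_null_bound,
      min_joint_strength = min_joint_strength(ci_null_bound)))
  out
}
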