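#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_contour geom_density
#'   geom_vline labs scale_fill_viridis_c facet_wrap theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Heat map of the bias grid
#'
#' Post-adjustment risk ratio over the lattice of joint confounder
#' strengths, with a contour at the null (risk ratio 1): combinations above
#' that contour would fully explain away the observed association.
#'
#' @param object a [bias_grid()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot bias_grid
#' @export
autoplot.bias_grid <- function(object, ...) {
  ggplot(object, aes(.data$rr_ue, .data$rr_ud, fill = .data$rr_post)) +
    geom_tile() +
    geom_contour(aes(z = .data$rr_post), breaks = 1, colour = "white") +
    scale_fill_viridis_c(trans = "log10") +
    labs(x = "confounder-exposure risk ratio",
         y = "confounder-outcome risk ratio",
         fill = "adjusted RR",
         title = sprintf("Bounding-factor adjustment of RR = %.2f",
                         attr(object, "rr_pre"))) +
    theme_minimal()
}

#' Propensity-score overlap plot
#'
#' Densities of the fitted propensity score by exposure arm — the standard
#' positivity/overlap diagnostic.
#'
#' @param cohort cohort with `ps` column (see [add_iptw()]).
#' @return a ggplot.
#' @export
plot_ps_overlap <- function(cohort) {
  stopifnot("ps" %in% names(cohort))
  d <- dplyr::mutate(as_tibble(cohort),
                     arm = factor(.data$exposure, c(0, 1),
                                  c("unexposed", "exposed")))
  ggplot(d, aes(.data$ps, fill = .data$arm)) +
    geom_density(alpha = 0.5) +
    labs(x = "propensity score", y = "density", fill = NULL) +
    theme_minimal()
}

#' Posterior densities of the two-step Bayesian effects
#'
#' @param object a `bayes_iptw` fit.
#' @param ... unused.
#' @return a ggplot with one panel per effect scale, HDI bounds marked.
#' @method autoplot bayes_iptw
#' @export
autoplot.bayes_iptw <- function(object, ...) {
  d <- tidyr::pivot_longer(object$effect_draws, c("rd", "rr"),
                           names_to = "scale", values_to = "value")
  hd <- tidy(object)
  hd$scale <- tolower(hd$scale)
  ggplot(d, aes(.data$value)) +
    geom_density() +
    geom_vline(data = tidyr::pivot_longer(hd, c("hdi_low", "hdi_high"),
                                          values_to = "bound"),
               aes(xintercept = .data$bound), linetype = 2) +
    facet_wrap(~scale, scales = "free") +
    labs(x = "posterior effect draw", y = "density") +
    theme_minimal()
}
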