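#' @importFrom rlang abort warn .data := %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats plogis qlogis qnorm pnorm rbinom runif rnorm glm binomial
#'   gaussian quasipoisson coef fitted var sd setNames
NULL

expit <- stats::plogis
logit <- stats::qlogis

#' Round half away from zero
#'
#' Fixed-decimal rounding with ties going up (0.05 -> 0.1), the convention
#' used for reporting participant-flow percentages. Base `round()` rounds
#' half to even, which disagrees on exact ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Derive independent per-stage seeds from one root seed; keeps every stage
# reproducible while stages stay order-insensitive. Seeds kept < 2^31.
derive_seeds <- function(seed, n_stages) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n_stages)
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

clip01 <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

z_crit <- function(ci_level) qnorm(1 - (1 - ci_level) / 2)

check_binary <- function(x, what) {
  if (anyNA(x)) abort(paste0("`", what, "` contains missing values"))
  if (!all(x %in% c(0, 1))) abort(paste0("`", what, "` must be coded 0/1"))
  invisible(as.numeric(x))
}
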