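#' Exposure-by-outcome counts
#'
#' Container for a 2x2 table in the epidemiological orientation:
#' `a` exposed cases, `b` exposed non-cases, `c` unexposed cases,
#' `d` unexposed non-cases.
#'
#' @param a,b,c,d non-negative integer counts.
#' @return a `two_by_two` object.
#' @export
#' @examples
#' two_by_two(2, 21, 7, 973)
two_by_two <- function(a, b, c, d) {
  cnt <- c(a = a, b = b, c = c, d = d)
  if (any(cnt < 0) || any(cnt != round(cnt))) abort("counts must be non-negative integers")
  if (a + b < 1 || c + d < 1) abort("each exposure arm needs at least one row")
  structure(as.list(cnt), class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(exposure = c("1", "0"), outcome = c("1", "0")))
  cat("2x2 exposure-by-outcome counts (n =", x$a + x$b + x$c + x$d, ")\n")
  print(m)
  invisible(x)
}

#' Published abruption counts from the motivating cohort
#'
#' The exposure-by-outcome cross-tabulation of heated-tobacco-product use in
#' the first trimester against placental abruption, as published for the
#' Japanese internet-survey cohort of 1003 pregnancies this package
#' re-analyses: 23 exposed (2 cases) and 980 unexposed (7 cases).
#'
#' @return a [two_by_two()] with a = 2, b = 21, c = 7, d = 973.
#' @export
#' @examples
#' crude_effects(abruption_two_by_two())
abruption_two_by_two <- function() two_by_two(2, 21, 7, 973)

#' Expand a 2x2 table to an individual-level cohort
#'
#' @param t a [two_by_two()].
#' @return a covariate-free `cohort_tbl` with one row per participant;
#'   tabulating it recovers the input counts exactly.
#' @export
expand_two_by_two <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  Z <- rep(c(1L, 1L, 0L, 0L), times = c(t$a, t$b, t$c, t$d))
  Y <- rep(c(1L, 0L, 1L, 0L), times = c(t$a, t$b, t$c, t$d))
  new_cohort_tbl(tibble(id = seq_along(Z), exposure = Z, outcome = Y))
}

#' Tabulate a cohort into 2x2 counts
#' @param cohort data frame with 0/1 `exposure` and `outcome` columns.
#' @return a [two_by_two()].
#' @export
tabulate_cohort <- function(cohort) {
  validate_cohort(cohort)
  z <- cohort$exposure; y <- cohort$outcome
  two_by_two(sum(z == 1 & y == 1), sum(z == 1 & y == 0),
             sum(z == 0 & y == 1), sum(z == 0 & y == 0))
}
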