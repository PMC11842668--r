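#' Read / write cohort tables as CSV
#'
#' Plain UTF-8 comma-separated files with a header row; 0/1 integer coding
#' for `exposure`, `outcome` and every covariate; optional `y0`, `y1`
#' synthetic-truth columns and `ps`, `iptw_weight` analysis columns. Lines
#' starting with `#` are provenance comments and are skipped on read.
#'
#' @param path file path.
#' @param cohort cohort tibble.
#' @param comment_lines optional character vector written as `#` comments
#'   before the header.
#' @return `read_cohort()` returns a validated `cohort_tbl`;
#'   `write_cohort()` returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  x <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  attr(x, "spec") <- NULL
  attr(x, "problems") <- NULL
  validate_cohort(x)
  new_cohort_tbl(x, covariate_names = setdiff(
    names(x), c("id", "exposure", "outcome", "y0", "y1", "ps", "iptw_weight")))
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path, comment_lines = NULL) {
  if (!is.null(comment_lines))
    writeLines(paste0("# ", comment_lines), path)
  readr::write_csv(cohort, path, append = !is.null(comment_lines),
                   col_names = TRUE)
  invisible(path)
}

provenance_header <- function(seed, config) {
  c(sprintf("iptwsens %s", as.character(utils::packageVersion("iptwsens"))),
    sprintf("seed: %s", if (is.null(seed)) "NA" else seed),
    sprintf("config_hash: %s", rlang::hash(config)))
}

resolve_cohort <- function(input) {
  if (inherits(input, "cohort_config")) return(generate_cohort(input))
  if (is.character(input)) return(read_cohort(input))
  validate_cohort(input)
  input
}

stage_log <- function(stage, ..., quiet = FALSE) {
  if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the frequentist IPTW analysis end to end
#'
#' Pipeline: validate the cohort (or generate/read it), fit the logistic
#' propensity model on the requested covariates, form ATE weights, and
#' estimate the weighted risk difference (identity-link Gaussian GLM) and
#' risk ratio (modified Poisson), both with HC0 sandwich standard errors,
#' alongside the crude contrasts. With no covariates the propensity model
#' is intercept-only and the weighted estimates collapse to the crude ones.
#'
#' @param input a cohort tibble, a CSV path, or a [cohort_config()].
#' @param covariates propensity-model covariates; default all covariate
#'   columns of the input (possibly none).
#' @param ci_level confidence level.
#' @param clip_eps propensity clipping bound.
#' @param out_dir optional output directory; when given, the weighted
#'   cohort (`cohort_weighted.csv`) and estimates (`estimates.csv`,
#'   `estimates.json`) are written with a provenance header carrying the
#'   package version, seed and config hash.
#' @param seed recorded in the provenance header (and used for generation
#'   when `input` is a config whose seed it overrides when non-NULL).
#' @param quiet suppress per-stage log lines.
#' @return list with `cohort` (including `ps`, `iptw_weight` columns),
#'   `ps_fit`, `estimates` (tidy tibble of crude and weighted effects) and
#'   `c_statistic`.
#' @export
#' @examples
#' res <- run_frequentist(expand_two_by_two(abruption_two_by_two()),
#'                        quiet = TRUE)
#' res$estimates
run_frequentist <- function(input, covariates = NULL, ci_level = 0.95,
                            clip_eps = 1e-6, out_dir = NULL, seed = NULL,
                            quiet = FALSE) {
  if (inherits(input, "cohort_config") && !is.null(seed))
    input$seed <- as.integer(seed)
  cohort <- resolve_cohort(input)
  if (is.null(covariates)) covariates <- cohort_covariates(cohort)
  missing_cov <- setdiff(covariates, names(cohort))
  if (length(missing_cov) > 0)
    abort(paste0("propensity stage: covariate column(s) missing from input: ",
                 paste(missing_cov, collapse = ", ")))
  n <- nrow(cohort); n_exposed <- sum(cohort$exposure)
  n_cases <- sum(cohort$outcome)
  stage_log("input", "n=%d exposed=%d cases=%d covariates=%d", n, n_exposed,
            n_cases, length(covariates), quiet = quiet)
  if (n_cases < 5)
    warn(sprintf("only %d cases: risk estimates may be unstable", n_cases))

  cohort <- add_iptw(cohort, covariates, clip_eps = clip_eps)
  fit <- attr(cohort, "ps_fit")
  cstat <- c_statistic(cohort$ps, cohort$exposure)
  stage_log("propensity", "converged=%s iterations=%d c_statistic=%.3f",
            fit$converged, fit$iterations, cstat, quiet = quiet)

  crude <- crude_effects(tabulate_cohort(cohort), ci_level)
  w <- cohort$iptw_weight
  wrd <- weighted_rd_glm(cohort$outcome, cohort$exposure, w, ci_level)
  wrr <- weighted_rr_modified_poisson(cohort$outcome, cohort$exposure, w,
                                      ci_level)
  estimates <- dplyr::bind_rows(
    dplyr::mutate(tidy(crude$rd), adjustment = "crude"),
    if (!is.null(crude$rr)) dplyr::mutate(tidy(crude$rr), adjustment = "crude"),
    dplyr::mutate(tidy(wrd), adjustment = "iptw"),
    dplyr::mutate(tidy(wrr), adjustment = "iptw")
  )
  stage_log("estimation", "iptw aRD=%.4f rRR=%.3f", wrd$point, wrr$point,
            quiet = quiet)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- provenance_header(seed, list(covariates = covariates,
                                        ci_level = ci_level,
                                        clip_eps = clip_eps))
    write_cohort(cohort, file.path(out_dir, "cohort_weighted.csv"), hdr)
    writeLines(paste0("# ", hdr), file.path(out_dir, "estimates.csv"))
    readr::write_csv(estimates, file.path(out_dir, "estimates.csv"),
                     append = TRUE, col_names = TRUE)
    jsonlite::write_json(
      list(provenance = as.list(hdr), c_statistic = cstat,
           estimates = estimates),
      file.path(out_dir, "estimates.json"), auto_unbox = TRUE, digits = NA)
  }
  list(cohort = cohort, ps_fit = fit, estimates = estimates,
       c_statistic = cstat)
}

#' Run the bounding-factor bias analysis
#'
#' @param rr_pre observed risk ratio (e.g. the IPTW rRR point estimate).
#' @param ci_null_bound optional confidence bound nearer the null.
#' @param axis_max,step grid controls, see [bias_grid()].
#' @param out_dir optional output directory for `bias_grid.csv` and
#'   `bias_summary.json`.
#' @param seed recorded in provenance (the analysis is deterministic).
#' @param quiet suppress log lines.
#' @return list with `grid` ([bias_grid()]) and `summary`
#'   ([bias_summary()]).
#' @export
run_bias <- function(rr_pre, ci_null_bound = NULL, axis_max = 15, step = 0.5,
                     out_dir = NULL, seed = NULL, quiet = FALSE) {
  if (missing(rr_pre) || is.null(rr_pre))
    abort("bias stage: `rr_pre` is required (point estimate of the rRR)")
  grid <- bias_grid(rr_pre, axis_max = axis_max, step = step)
  summ <- bias_summary(rr_pre, ci_null_bound)
  stage_log("bias", "rr_pre=%.3f evalue_point=%.2f%s", rr_pre,
            summ$min_joint_strength[1],
            if (!is.null(ci_null_bound))
              sprintf(" evalue_ci_bound=%.2f", summ$min_joint_strength[2])
            else "", quiet = quiet)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- provenance_header(seed, list(rr_pre = rr_pre,
                                        ci_null_bound = ci_null_bound,
                                        axis_max = axis_max, step = step))
    writeLines(paste0("# ", hdr), file.path(out_dir, "bias_grid.csv"))
    readr::write_csv(tibble::as_tibble(grid),
                     file.path(out_dir, "bias_grid.csv"),
                     append = TRUE, col_names = TRUE)
    jsonlite::write_json(
      list(provenance = as.list(hdr), rr_pre = rr_pre, summary = summ),
      file.path(out_dir, "bias_summary.json"), auto_unbox = TRUE, digits = NA)
  }
  list(grid = grid, summary = summ)
}

#' Participant-flow percentages
#'
#' Recomputes each stage's percentage of its stated denominator, rounded
#' half-up to one decimal — the reporting convention of study flow
#' diagrams.
#'
#' @param counts tibble/data frame with columns `stage`, `count`,
#'   `denominator`.
#' @return the input with a `percent` column.
#' @export
#' @examples
#' flow_report(survey_flow_counts())
flow_report <- function(counts) {
  stopifnot(all(c("stage", "count", "denominator") %in% names(counts)))
  if (any(counts$count < 0)) abort("counts must be non-negative")
  if (any(counts$denominator <= 0)) abort("denominators must be positive")
  dplyr::mutate(as_tibble(counts),
                percent = round_half_up(100 * .data$count / .data$denominator, 1))
}

#' Participant flow of the motivating survey cohort
#'
#' Published stage counts of the internet-survey cohort: invitations,
#' responses, fraud exclusions, eligibility, pregnancy screening, follow-up
#' and the final analysis set of 1003. Denominators follow the published
#' reporting (the pregnancy-screening stage is a percentage of eligible
#' respondents; all others of the initial invitations).
#'
#' @return tibble with `stage`, `count`, `denominator`.
#' @export
survey_flow_counts <- function() {
  tibble(
    stage = c("responses", "fraudulent_excluded", "eligible", "pregnant",
              "followup_excluded", "followup_responses", "still_pregnant_excluded",
              "analyzed"),
    count = c(8536, 489, 8047, 1780, 435, 1345, 342, 1003),
    denominator = c(14086, 14086, 14086, 8047, 14086, 14086, 14086, 14086)
  )
}
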