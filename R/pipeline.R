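#' Summarize a cohort
#'
#' Counts, OCMB positivity, optional sex/activity tallies, and median (IQR)
#' of the index values. Percentages use the report convention (integer,
#' half away from zero); quantiles use linear interpolation (type 7).
#'
#' @param cohort Cohort or panel data frame (non-empty).
#' @return A list of class `"cohort_summary"`.
#' @export
cohort_summary <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) {
    stop("'cohort' must be a non-empty data frame", call. = FALSE)
  }
  n <- nrow(cohort)
  count_pct <- function(x) {
    k <- sum(x == 1, na.rm = TRUE)
    list(count = k, percent = pct(k / n),
         label = sprintf("%d (%d %%)", k, pct(k / n)))
  }
  med_iqr <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, na.rm = TRUE)
    list(median = unname(q[2]), iqr = unname(q[3] - q[1]))
  }
  out <- list(n = n)
  if ("ocmb_status" %in% names(cohort)) {
    out$ocmb_positive <- count_pct(cohort$ocmb_status)
  }
  if ("activity" %in% names(cohort)) {
    out$active <- count_pct(cohort$activity)
  }
  if ("sex" %in% names(cohort)) {
    out$male <- count_pct(cohort$sex == "M" | cohort$sex == 1)
  }
  for (idx in intersect(c("qalb", "igmi", "fklci"), names(cohort))) {
    out[[idx]] <- med_iqr(cohort[[idx]])
  }
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort: n =", x$n, "\n")
  if (!is.null(x$ocmb_positive)) {
    cat("  OCMB positive:", x$ocmb_positive$label, "\n")
  }
  if (!is.null(x$male)) cat("  male:", x$male$label, "\n")
  if (!is.null(x$active)) cat("  disease activity:", x$active$label, "\n")
  for (idx in intersect(c("qalb", "igmi", "fklci"), names(x))) {
    cat(sprintf("  %s: median %.3g (IQR %.3g)\n", idx,
                x[[idx]]$median, x[[idx]]$iqr))
  }
  invisible(x)
}

#' Run the full triage pipeline and write its artifacts
#'
#' End-to-end orchestration: ingest a cohort CSV or simulate one, derive the
#' index panel, fit the triage rule ([ocmb_triage()]), and write a complete,
#' reproducible artifact set to `out_dir`:
#' \describe{
#'   \item{`cohort.csv`}{the analyzed cohort (canonical dialect).}
#'   \item{`summary.json`}{[cohort_summary()] output.}
#'   \item{`roc.json`}{AUCs with DeLong CIs, the paired comparison,
#'     Spearman correlation, and the selected cutoffs.}
#'   \item{`grid.csv`}{the full rule-evaluation table (raw fractions).}
#'   \item{`model.json`}{the selected optimal rule.}
#'   \item{`run.json`}{configuration echo: seed, parameters, package
#'     version, for provenance.}
#' }
#' Outputs are deterministic given the same configuration and seed.
#'
#' @param input Path to a cohort CSV, or `NULL` to simulate.
#' @param params A [cohort_params()] object used when `input` is `NULL`.
#' @param seed Integer seed (required when simulating; echoed always).
#' @param out_dir Output directory (created if needed).
#' @param min_specificity,snap_igmi,snap_fklci,level,ci_method Passed to
#'   [ocmb_triage()].
#' @param units Optional unit map passed to [read_cohort()].
#' @param quiet Suppress progress messages.
#' @return The fitted `"ocmb_triage"` object, invisibly, with an
#'   `artifacts` attribute listing the files written.
#' @export
run_pipeline <- function(input = NULL, params = cohort_params(), seed = NULL,
                         out_dir = "ocmb-run", min_specificity = 0.85,
                         snap_igmi = 0.05, snap_fklci = 25, level = 0.95,
                         ci_method = "clopper-pearson", units = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message("[ocmbtriage] ", ...)
  if (is.null(input) && is.null(seed)) {
    stop("simulation requires a 'seed'", call. = FALSE)
  }
  if (!is.null(input) && !file.exists(input)) {
    stop("input file not found: ", input, call. = FALSE)
  }
  cohort <- if (is.null(input)) {
    say("simulating cohort: n = ", params$n, ", seed = ", seed)
    simulate_cohort(params, seed = seed)
  } else {
    say("reading cohort from ", input)
    read_cohort(input, units = units)
  }
  say("fitting triage rule")
  fit <- ocmb_triage(cohort, min_specificity = min_specificity,
                     snap_igmi = snap_igmi, snap_fklci = snap_fklci,
                     level = level, ci_method = ci_method)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c(cohort = "cohort.csv",
                                summary = "summary.json",
                                roc = "roc.json", grid = "grid.csv",
                                model = "model.json", run = "run.json"))
  names(paths) <- c("cohort", "summary", "roc", "grid", "model", "run")
  write_cohort(fit$panel, paths["cohort"])
  write_json_artifact(unclass(cohort_summary(fit$panel)), paths["summary"])
  write_json_artifact(list(
    auc = list(igmi = unclass(fit$roc$igmi$estimate),
               fklci = unclass(fit$roc$fklci$estimate)),
    comparison = fit$comparison,
    correlation = fit$correlation,
    cutoffs = fit$cutoffs,
    min_specificity = min_specificity
  ), paths["roc"])
  utils::write.csv(as.data.frame(fit$grid), paths["grid"],
                   row.names = FALSE)
  write_json_artifact(unclass(fit$optimal), paths["model"])
  write_json_artifact(list(
    seed = seed, input = input,
    params = if (is.null(input)) unclass(params) else NULL,
    min_specificity = min_specificity, snap_igmi = snap_igmi,
    snap_fklci = snap_fklci, level = level, ci_method = ci_method,
    package_version = as.character(utils::packageVersion("ocmbtriage"))
  ), paths["run"])
  say("selected model ", fit$optimal$name, ": IgMi >= ",
      fit$optimal$igmi_cutoff, " or FKLCi >= ", fit$optimal$fklci_cutoff)
  say("artifacts written to ", normalizePath(out_dir))
  attr(fit, "artifacts") <- paths
  invisible(fit)
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}
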