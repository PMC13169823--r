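#' Two-marker OR decision model
#'
#' A triage rule defined by a pair of cutoffs: predict OCMB-positive (and
#' skip confirmatory OCMB testing) when `igmi >= igmi_cutoff` OR
#' `fklci >= fklci_cutoff`; otherwise route the patient to OCMB testing.
#' Comparisons are inclusive throughout.
#'
#' @param igmi_cutoff,fklci_cutoff Strictly positive thresholds.
#' @param name Model label (e.g. `"C"`).
#' @return An object of class `"decision_model"`.
#' @examples
#' decision_model(0.2, 250, name = "C")
#' @export
decision_model <- function(igmi_cutoff, fklci_cutoff, name = NULL) {
  check_positive(igmi_cutoff, "igmi_cutoff")
  check_positive(fklci_cutoff, "fklci_cutoff")
  if (is.null(name)) {
    name <- sprintf("IgMi>=%g|FKLCi>=%g", igmi_cutoff, fklci_cutoff)
  }
  structure(list(name = as.character(name),
                 igmi_cutoff = igmi_cutoff,
                 fklci_cutoff = fklci_cutoff),
            class = "decision_model")
}

#' @export
print.decision_model <- function(x, ...) {
  cat(sprintf("Model %s: flag if IgMi >= %g or FKLCi >= %g\n",
              x$name, x$igmi_cutoff, x$fklci_cutoff))
  invisible(x)
}

#' Apply a decision model to index panels
#'
#' @param panel A data frame with `igmi` and `fklci` columns (e.g. from
#'   [compute_panel()]).
#' @param model A [decision_model()].
#' @return Logical vector: `TRUE` = flagged OCMB-positive (test spared),
#'   `FALSE` = route to OCMB testing.
#' @export
apply_rule <- function(panel, model) {
  stopifnot(inherits(model, "decision_model"))
  if (!all(c("igmi", "fklci") %in% names(panel))) {
    stop("'panel' must contain 'igmi' and 'fklci' columns", call. = FALSE)
  }
  panel$igmi >= model$igmi_cutoff | panel$fklci >= model$fklci_cutoff
}

#' Confusion counts for a decision model on a labeled cohort
#'
#' @param panel A data frame with `igmi`, `fklci` and a known binary
#'   `ocmb_status` for every row.
#' @param model A [decision_model()].
#' @return A list of class `"confusion_counts"` with integer fields `tp`,
#'   `fp`, `fn`, `tn` summing to `nrow(panel)`.
#' @export
confusion_counts <- function(panel, model) {
  if (!"ocmb_status" %in% names(panel)) {
    stop("'panel' must contain an 'ocmb_status' column", call. = FALSE)
  }
  if (anyNA(panel$ocmb_status)) {
    ids <- if ("patient_id" %in% names(panel)) {
      panel$patient_id[is.na(panel$ocmb_status)]
    } else {
      which(is.na(panel$ocmb_status))
    }
    stop("missing OCMB label for sample(s): ", paste(ids, collapse = ", "),
         "; filter unlabeled samples before computing counts", call. = FALSE)
  }
  flagged <- apply_rule(panel, model)
  truth <- as.logical(panel$ocmb_status)
  structure(list(tp = sum(flagged & truth),
                 fp = sum(flagged & !truth),
                 fn = sum(!flagged & truth),
                 tn = sum(!flagged & !truth)),
            class = "confusion_counts")
}

#' Binomial proportion confidence interval
#'
#' Exact Clopper--Pearson interval from beta quantiles (the default), or the
#' Wilson score interval. At the boundaries the exact interval is
#' `(0, upper)` for zero successes and `(lower, 1)` for all successes.
#'
#' @param successes,n Non-negative integer counts with `successes <= n`,
#'   `n >= 1`.
#' @param level Confidence level (default 0.95).
#' @param method `"clopper-pearson"` (exact, conservative; the package
#'   default for small diagnostic cohorts) or `"wilson"`.
#' @return Numeric vector `c(low, high)`.
#' @examples
#' proportion_ci(40, 43)
#' @export
proportion_ci <- function(successes, n, level = 0.95,
                          method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  if (!is.numeric(successes) || !is.numeric(n) ||
      length(successes) != 1L || length(n) != 1L ||
      anyNA(c(successes, n)) || n < 1 || successes < 0 || successes > n ||
      successes != round(successes) || n != round(n)) {
    stop("'successes' and 'n' must be integers with 0 <= successes <= n, ",
         "n >= 1", call. = FALSE)
  }
  if (level <= 0 || level >= 1) {
    stop("'level' must lie strictly inside (0, 1)", call. = FALSE)
  }
  alpha <- 1 - level
  if (method == "clopper-pearson") {
    low <- if (successes == 0) 0 else {
      stats::qbeta(alpha / 2, successes, n - successes + 1)
    }
    high <- if (successes == n) 1 else {
      stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
    }
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    p <- successes / n
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    low <- max(0, centre - half)
    high <- min(1, centre + half)
  }
  c(low = low, high = high)
}

#' Diagnostic accuracy report from confusion counts
#'
#' Sensitivity, specificity, PPV and NPV with binomial confidence intervals,
#' plus the test-sparing statistic PROM (percentage reduction of OCMB
#' measurements): the fraction of patients flagged by the rule — who would
#' skip confirmatory testing — over all patients, `(tp + fp) / n_total`.
#' PROM is reported without a confidence interval. A metric with a zero
#' denominator (e.g. PPV when nothing is flagged) is reported as `NA` with
#' the `undefined` field naming it, not as an error.
#'
#' @param counts A [confusion_counts()] object.
#' @param level Confidence level for the intervals.
#' @param ci_method Passed to [proportion_ci()].
#' @return An object of class `"diagnostic_report"`: list with `counts`,
#'   `n_total`, `prevalence`, one `list(estimate, ci_low, ci_high)` per
#'   metric, `prom`, and `undefined` (character vector of metrics with zero
#'   denominator).
#' @export
diagnostics <- function(counts, level = 0.95,
                        ci_method = c("clopper-pearson", "wilson")) {
  stopifnot(inherits(counts, "confusion_counts"))
  ci_method <- match.arg(ci_method)
  n_total <- counts$tp + counts$fp + counts$fn + counts$tn
  if (n_total < 1) stop("empty confusion counts", call. = FALSE)
  metric <- function(successes, denom) {
    if (denom == 0) {
      return(list(estimate = NA_real_, ci_low = NA_real_,
                  ci_high = NA_real_))
    }
    ci <- proportion_ci(successes, denom, level, ci_method)
    list(estimate = successes / denom,
         ci_low = unname(ci["low"]), ci_high = unname(ci["high"]))
  }
  out <- list(
    counts = counts,
    n_total = n_total,
    prevalence = (counts$tp + counts$fn) / n_total,
    sensitivity = metric(counts$tp, counts$tp + counts$fn),
    specificity = metric(counts$tn, counts$tn + counts$fp),
    ppv = metric(counts$tp, counts$tp + counts$fp),
    npv = metric(counts$tn, counts$tn + counts$fn),
    prom = (counts$tp + counts$fp) / n_total,
    level = level,
    ci_method = ci_method
  )
  out$undefined <- names(which(vapply(
    out[c("sensitivity", "specificity", "ppv", "npv")],
    function(m) is.na(m$estimate), logical(1)
  )))
  structure(out, class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  fmt <- function(m) {
    if (is.na(m$estimate)) return("undefined")
    sprintf("%d (%d-%d)", pct(m$estimate), pct(m$ci_low), pct(m$ci_high))
  }
  cat(sprintf("n = %d (tp %d, fp %d, fn %d, tn %d)\n", x$n_total,
              x$counts$tp, x$counts$fp, x$counts$fn, x$counts$tn))
  cat("Sensitivity, %: ", fmt(x$sensitivity), "\n", sep = "")
  cat("Specificity, %: ", fmt(x$specificity), "\n", sep = "")
  cat("PPV, %:         ", fmt(x$ppv), "\n", sep = "")
  cat("NPV, %:         ", fmt(x$npv), "\n", sep = "")
  cat("PROM, %:        ", pct(x$prom), "\n", sep = "")
  invisible(x)
}

# Integer percentage, rounding half away from zero (report convention;
# base round() rounds half to even).
pct <- function(x) {
  as.integer(sign(x) * floor(abs(x) * 100 + 0.5))
}

#' Evaluate single-marker cutoffs and two-marker models on a cohort
#'
#' Produces one report row per single-marker cutoff (that marker alone
#' `>= cutoff`) and per two-marker OR model, in the style of a diagnostic
#' accuracy table: confusion counts, sensitivity/specificity/PPV/NPV with
#' confidence intervals, and PROM.
#'
#' @param panel Labeled panel data frame (`igmi`, `fklci`, `ocmb_status`).
#' @param models List of [decision_model()] objects (non-empty).
#' @param igmi_cutoffs,fklci_cutoffs Single-marker cutoffs to report
#'   alongside the models (optional).
#' @param level,ci_method Passed to [diagnostics()].
#' @return A data frame of class `"triage_grid"`, one row per rule, with
#'   raw fractions (machine-readable) retained; the print method shows
#'   integer percentages.
#' @export
evaluate_grid <- function(panel, models,
                          igmi_cutoffs = numeric(), fklci_cutoffs = numeric(),
                          level = 0.95,
                          ci_method = c("clopper-pearson", "wilson")) {
  ci_method <- match.arg(ci_method)
  if (length(models) == 0L && length(igmi_cutoffs) == 0L &&
      length(fklci_cutoffs) == 0L) {
    stop("nothing to evaluate: no models or single-marker cutoffs",
         call. = FALSE)
  }
  if (inherits(models, "decision_model")) models <- list(models)
  rules <- c(
    lapply(igmi_cutoffs, function(ct) {
      # single-marker rule via an unreachable partner cutoff
      list(type = "IgMi", label = format(ct),
           model = decision_model(ct, Inf_cutoff(panel$fklci),
                                  name = paste0("IgMi ", format(ct))))
    }),
    lapply(fklci_cutoffs, function(ct) {
      list(type = "FKLCi", label = format(ct),
           model = decision_model(Inf_cutoff(panel$igmi), ct,
                                  name = paste0("FKLCi ", format(ct))))
    }),
    lapply(models, function(m) {
      stopifnot(inherits(m, "decision_model"))
      list(type = "model", label = m$name, model = m)
    })
  )
  rows <- lapply(rules, function(rule) {
    rep <- diagnostics(confusion_counts(panel, rule$model), level, ci_method)
    data.frame(
      name = rule$model$name, type = rule$type,
      igmi_cutoff = rule$model$igmi_cutoff,
      fklci_cutoff = rule$model$fklci_cutoff,
      tp = rep$counts$tp, fp = rep$counts$fp,
      fn = rep$counts$fn, tn = rep$counts$tn,
      sensitivity = rep$sensitivity$estimate,
      sens_low = rep$sensitivity$ci_low, sens_high = rep$sensitivity$ci_high,
      specificity = rep$specificity$estimate,
      spec_low = rep$specificity$ci_low, spec_high = rep$specificity$ci_high,
      ppv = rep$ppv$estimate,
      ppv_low = rep$ppv$ci_low, ppv_high = rep$ppv$ci_high,
      npv = rep$npv$estimate,
      npv_low = rep$npv$ci_low, npv_high = rep$npv$ci_high,
      prom = rep$prom,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("triage_grid", "data.frame")
  out
}

# A cutoff strictly above every observed value: the partner marker never
# fires, reducing the OR rule to a single-marker rule.
Inf_cutoff <- function(values) {
  max(values) * 2 + 1
}

#' @export
print.triage_grid <- function(x, ...) {
  fmt_ci <- function(est, lo, hi) {
    ifelse(is.na(est), "undef",
           sprintf("%d (%d-%d)", pct(est), pct(lo), pct(hi)))
  }
  shown <- data.frame(
    Rule = x$name,
    `Specificity, %` = fmt_ci(x$specificity, x$spec_low, x$spec_high),
    `Sensitivity, %` = fmt_ci(x$sensitivity, x$sens_low, x$sens_high),
    `PPV, %` = fmt_ci(x$ppv, x$ppv_low, x$ppv_high),
    `NPV, %` = fmt_ci(x$npv, x$npv_low, x$npv_high),
    `PROM, %` = pct(x$prom),
    check.names = FALSE
  )
  print(shown, row.names = FALSE)
  invisible(x)
}

#' Select the optimal decision model from a report table
#'
#' Lexicographic ranking of the two-marker models: maximize specificity,
#' then PPV, then PROM, with a deterministic final tie-break on model name.
#' This formalizes the clinical preference for a high-confidence,
#' test-sparing triage rule: first make false positives rare, then make a
#' positive flag trustworthy, then spare as many confirmatory tests as
#' possible. Any table containing `name`, `specificity`, `ppv` and `prom`
#' columns is accepted.
#'
#' @param grid A [evaluate_grid()] table (rows with `type == "model"` are
#'   ranked when a `type` column is present; otherwise all rows).
#' @return The winning row's name and cutoffs as a list; the cutoffs are
#'   `NA` if the table carries none.
#' @export
select_optimal <- function(grid) {
  if (!is.data.frame(grid) || nrow(grid) == 0L) {
    stop("'grid' must be a non-empty data frame", call. = FALSE)
  }
  needed <- c("name", "specificity", "ppv", "prom")
  if (!all(needed %in% names(grid))) {
    stop("'grid' must contain columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  cand <- if ("type" %in% names(grid)) {
    grid[grid$type == "model", , drop = FALSE]
  } else {
    grid
  }
  if (nrow(cand) == 0L) {
    stop("'grid' contains no two-marker model rows", call. = FALSE)
  }
  ord <- order(-cand$specificity, -cand$ppv, -cand$prom, cand$name)
  best <- cand[ord[1], , drop = FALSE]
  list(name = best$name,
       igmi_cutoff = if ("igmi_cutoff" %in% names(best)) {
         best$igmi_cutoff
       } else NA_real_,
       fklci_cutoff = if ("fklci_cutoff" %in% names(best)) {
         best$fklci_cutoff
       } else NA_real_,
       specificity = best$specificity, ppv = best$ppv, prom = best$prom)
}
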