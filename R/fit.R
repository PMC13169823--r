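#' Fit an OCMB triage rule to a labeled cohort
#'
#' The main entry point. From a cohort of paired CSF/serum samples with
#' known oligoclonal IgM band (OCMB) status, this function
#' \enumerate{
#'   \item derives the albumin-normalized indices IgMi and FKLCi
#'     ([compute_panel()]), unless the panel columns are already present;
#'   \item builds the empirical ROC curve of each marker against OCMB
#'     status, with DeLong confidence intervals and the paired DeLong
#'     comparison of the two AUCs;
#'   \item selects, per marker, the cutoff maximizing sensitivity subject to
#'     specificity strictly above `min_specificity`, snapped up to a round
#'     clinical grid ([select_cutoff()]);
#'   \item evaluates a grid of candidate rules — each marker alone at each
#'     candidate cutoff, and every two-marker OR combination
#'     ([evaluate_grid()]); by default the candidates per marker are the
#'     constrained-optimal cutoff and the next grid step up, yielding four
#'     OR models labeled A--D;
#'   \item picks the optimal OR rule by lexicographic
#'     (specificity, PPV, PROM) ranking ([select_optimal()]).
#' }
#'
#' @param data A cohort data frame: either raw concentrations (see
#'   [compute_panel()]) or a ready panel with `igmi` and `fklci`, plus
#'   `ocmb_status` (rows with `NA` status are dropped with a message).
#' @param min_specificity Strict specificity floor for cutoff selection.
#' @param snap_igmi,snap_fklci Grid steps for cutoff snapping (`NULL` to
#'   disable). Defaults 0.05 and 25 reproduce round clinical cutoffs.
#' @param models Optional list of [decision_model()] objects to evaluate
#'   instead of the default A--D grid built from the selected cutoffs.
#' @param level Confidence level for all intervals.
#' @param ci_method `"clopper-pearson"` (default) or `"wilson"`.
#' @return An object of class `"ocmb_triage"` with components `panel`,
#'   `roc` (per-marker curve and [delong_ci()] estimate), `comparison`
#'   (paired [delong_test()]), `correlation` (Spearman), `cutoffs`,
#'   `candidates`, `grid` (the [evaluate_grid()] table), `optimal`
#'   (the winning [decision_model()]), and the call/configuration.
#'   Supports `print`, `summary`, `coef`, `predict`, `plot` and
#'   `simulate`.
#' @examples
#' cohort <- simulate_cohort(cohort_params(), seed = 7)
#' fit <- ocmb_triage(cohort)
#' fit
#' coef(fit)
#' @export
ocmb_triage <- function(data, min_specificity = 0.85,
                        snap_igmi = 0.05, snap_fklci = 25,
                        models = NULL, level = 0.95,
                        ci_method = c("clopper-pearson", "wilson")) {
  ci_method <- match.arg(ci_method)
  panel <- if (all(c("igmi", "fklci") %in% names(data))) {
    data
  } else {
    compute_panel(data)
  }
  if (!"ocmb_status" %in% names(panel)) {
    stop("'data' must carry an 'ocmb_status' label column", call. = FALSE)
  }
  if (anyNA(panel$ocmb_status)) {
    message("Dropping ", sum(is.na(panel$ocmb_status)),
            " sample(s) without an OCMB label")
    panel <- panel[!is.na(panel$ocmb_status), , drop = FALSE]
  }
  status <- as.logical(panel$ocmb_status)
  if (!any(status) || all(status)) {
    stop("need both OCMB-positive and OCMB-negative samples", call. = FALSE)
  }

  roc <- lapply(c(igmi = "igmi", fklci = "fklci"), function(marker) {
    scores <- panel[[marker]]
    list(curve = roc_curve(scores, status),
         estimate = delong_ci(scores[status], scores[!status], level))
  })
  comparison <- delong_test(panel$igmi, panel$fklci, status)
  correlation <- rank_correlation(panel$igmi, panel$fklci)

  cutoffs <- list(
    igmi = select_cutoff(roc$igmi$curve, min_specificity, snap_igmi),
    fklci = select_cutoff(roc$fklci$curve, min_specificity, snap_fklci)
  )
  # Candidate cutoffs: the constrained optimum and one grid step tighter.
  step_up <- function(sel, grid) {
    c(sel$threshold,
      if (!is.null(grid)) sel$threshold + grid else sel$threshold * 1.5)
  }
  candidates <- list(igmi = step_up(cutoffs$igmi, snap_igmi),
                     fklci = step_up(cutoffs$fklci, snap_fklci))
  if (is.null(models)) {
    models <- list(
      decision_model(candidates$igmi[1], candidates$fklci[1], name = "A"),
      decision_model(candidates$igmi[2], candidates$fklci[2], name = "B"),
      decision_model(candidates$igmi[1], candidates$fklci[2], name = "C"),
      decision_model(candidates$igmi[2], candidates$fklci[1], name = "D")
    )
  }
  grid <- evaluate_grid(panel, models,
                        igmi_cutoffs = candidates$igmi,
                        fklci_cutoffs = candidates$fklci,
                        level = level, ci_method = ci_method)
  best <- select_optimal(grid)
  optimal <- models[[match(best$name, vapply(models, `[[`, "", "name"))]]

  structure(list(call = match.call(),
                 panel = panel,
                 n = nrow(panel), n_pos = sum(status), n_neg = sum(!status),
                 roc = roc, comparison = comparison,
                 correlation = correlation,
                 cutoffs = cutoffs, candidates = candidates,
                 models = models, grid = grid, optimal = optimal,
                 min_specificity = min_specificity,
                 level = level, ci_method = ci_method),
            class = "ocmb_triage")
}

#' @export
print.ocmb_triage <- function(x, ...) {
  cat("OCMB triage rule\n")
  cat(sprintf("  cohort: n = %d (%d OCMB+, %d OCMB-; prevalence %d%%)\n",
              x$n, x$n_pos, x$n_neg, pct(x$n_pos / x$n)))
  cat(sprintf("  AUC IgMi %.2f (%.2f-%.2f), FKLCi %.2f (%.2f-%.2f)\n",
              x$roc$igmi$estimate$auc, x$roc$igmi$estimate$ci_low,
              x$roc$igmi$estimate$ci_high,
              x$roc$fklci$estimate$auc, x$roc$fklci$estimate$ci_low,
              x$roc$fklci$estimate$ci_high))
  cat(sprintf("  selected rule %s: flag if IgMi >= %g or FKLCi >= %g\n",
              x$optimal$name, x$optimal$igmi_cutoff, x$optimal$fklci_cutoff))
  row <- x$grid[x$grid$name == x$optimal$name, ]
  cat(sprintf("  specificity %d%%, PPV %d%%, PROM %d%%\n",
              pct(row$specificity), pct(row$ppv), pct(row$prom)))
  invisible(x)
}

#' @export
summary.ocmb_triage <- function(object, ...) {
  structure(object, class = c("summary.ocmb_triage", "ocmb_triage"))
}

#' @export
print.summary.ocmb_triage <- function(x, ...) {
  print.ocmb_triage(x)
  cat(sprintf("\nSpearman rho(IgMi, FKLCi) = %.2f (p = %.2g)\n",
              x$correlation$rho, x$correlation$p_value))
  cat(sprintf("Paired DeLong AUC comparison: z = %.2f, p = %.2g\n",
              x$comparison$statistic, x$comparison$p_value))
  cat(sprintf("\nCutoff candidates (specificity > %d%%): IgMi %s; FKLCi %s\n",
              pct(x$min_specificity),
              paste(format(x$candidates$igmi), collapse = ", "),
              paste(format(x$candidates$fklci), collapse = ", ")))
  cat("\nRule grid:\n")
  print(x$grid)
  invisible(x)
}

#' @export
coef.ocmb_triage <- function(object, ...) {
  c(igmi_cutoff = object$optimal$igmi_cutoff,
    fklci_cutoff = object$optimal$fklci_cutoff)
}

#' Predict triage routing for new patients
#'
#' Applies the fitted OR rule to new samples.
#'
#' @param object A fitted [ocmb_triage()] object.
#' @param newdata Cohort or panel data frame; defaults to the training
#'   panel.
#' @param type `"class"` for a factor with levels `"skip_ocmb_test"`
#'   (predicted OCMB-positive) and `"perform_ocmb_test"`, or `"flag"` for
#'   the raw logical.
#' @param ... Unused.
#' @return Factor or logical vector, one element per sample.
#' @export
predict.ocmb_triage <- function(object, newdata = NULL,
                                type = c("class", "flag"), ...) {
  type <- match.arg(type)
  panel <- if (is.null(newdata)) {
    object$panel
  } else if (all(c("igmi", "fklci") %in% names(newdata))) {
    newdata
  } else {
    compute_panel(newdata)
  }
  flag <- apply_rule(panel, object$optimal)
  if (type == "flag") return(flag)
  factor(ifelse(flag, "skip_ocmb_test", "perform_ocmb_test"),
         levels = c("skip_ocmb_test", "perform_ocmb_test"))
}

#' Plot the marker ROC curves of a fitted triage rule
#'
#' Draws both empirical ROC curves with the selected cutoffs marked.
#'
#' @param x A fitted [ocmb_triage()] object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ocmb_triage <- function(x, ...) {
  graphics::plot(1 - x$roc$igmi$curve$specificities,
                 x$roc$igmi$curve$sensitivities,
                 type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 col = "firebrick", lwd = 2,
                 main = "Marker ROC curves for OCMB positivity", ...)
  graphics::lines(1 - x$roc$fklci$curve$specificities,
                  x$roc$fklci$curve$sensitivities,
                  type = "s", col = "steelblue", lwd = 2)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  for (m in c("igmi", "fklci")) {
    sel <- x$cutoffs[[m]]
    graphics::points(1 - sel$specificity, sel$sensitivity, pch = 19,
                     col = if (m == "igmi") "firebrick" else "steelblue")
  }
  graphics::legend(
    "bottomright", bty = "n", lwd = 2, col = c("firebrick", "steelblue"),
    legend = c(sprintf("IgMi: AUC %.2f", x$roc$igmi$estimate$auc),
               sprintf("FKLCi: AUC %.2f", x$roc$fklci$estimate$auc))
  )
  invisible(x)
}

#' Simulate cohorts from a fitted triage rule
#'
#' Parametric bootstrap: estimates the log-normal cohort model from the
#' training panel (class-wise log-means of the two indices, pooled
#' within-class log-sd, within-class Pearson correlation of the logs,
#' observed prevalence) and draws new cohorts from it with
#' [simulate_cohort()]. Serum and albumin-quotient parameters fall back to
#' the generator defaults when the training data carry no concentrations.
#'
#' @param object A fitted [ocmb_triage()] object.
#' @param nsim Number of cohorts to draw.
#' @param seed Integer seed (required).
#' @param n Size of each simulated cohort; defaults to the training size.
#' @param ... Unused.
#' @return A list of `nsim` cohort data frames.
#' @export
simulate.ocmb_triage <- function(object, nsim = 1, seed, n = object$n, ...) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  status <- as.logical(object$panel$ocmb_status)
  lg <- log(cbind(object$panel$igmi, object$panel$fklci))
  mu_neg <- colMeans(lg[!status, , drop = FALSE])
  mu_pos <- colMeans(lg[status, , drop = FALSE])
  centered <- lg
  centered[status, ] <- sweep(lg[status, , drop = FALSE], 2, mu_pos)
  centered[!status, ] <- sweep(lg[!status, , drop = FALSE], 2, mu_neg)
  sigma <- apply(centered, 2, stats::sd)
  rho <- stats::cor(centered[, 1], centered[, 2])
  params <- cohort_params(n = n, prevalence = mean(status),
                          log_mu_neg = mu_neg, log_sigma = sigma,
                          delta = mu_pos - mu_neg, rho = rho)
  lapply(seq_len(nsim), function(i) {
    simulate_cohort(params, seed = as.integer(seed) + i - 1L)
  })
}
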