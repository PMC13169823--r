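#' Empirical (Mann--Whitney) AUC
#'
#' The probability that a randomly chosen positive-class score exceeds a
#' randomly chosen negative-class score, with ties counted one half:
#' the mean of \eqn{\psi(x_i, y_j)} over all positive/negative pairs, where
#' \eqn{\psi = 1} if \eqn{x > y}, \eqn{1/2} if \eqn{x = y}, \eqn{0}
#' otherwise. Computed via mid-ranks in \eqn{O(N \log N)}.
#'
#' @param pos_scores Scores of the positive class (non-empty).
#' @param neg_scores Scores of the negative class (non-empty).
#' @return The AUC as a single number in \[0, 1\].
#' @examples
#' empirical_auc(c(2, 3), 1)        # 1
#' empirical_auc(c(1, 2), c(1, 3))  # 0.375
#' @export
empirical_auc <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L) {
    stop("both classes must contain at least one score", call. = FALSE)
  }
  if (anyNA(pos_scores) || anyNA(neg_scores)) {
    stop("scores must not contain missing values", call. = FALSE)
  }
  m <- length(pos_scores)
  n <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Empirical ROC curve
#'
#' Sweeps the inclusive decision rule `score >= threshold => predicted
#' positive` over every unique score (plus an `Inf` sentinel, giving the
#' (sens 0, spec 1) corner), recording sensitivity and specificity at each
#' operating point. The trapezoidal area under the resulting curve equals
#' the Mann--Whitney AUC.
#'
#' @param scores Numeric marker values.
#' @param labels Binary class labels (0/1 or logical), same length.
#' @return An object of class `"roc_curve"`: a list with `thresholds`
#'   (descending, `Inf` first), `sensitivities`, `specificities`, `auc`,
#'   and the class sizes `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("'scores' and 'labels' must have equal length", call. = FALSE)
  }
  if (anyNA(scores) || anyNA(labels)) {
    stop("scores and labels must not contain missing values", call. = FALSE)
  }
  labels <- as.integer(as.logical(labels))
  if (!any(labels == 1L) || !any(labels == 0L)) {
    stop("both classes must be present in 'labels'", call. = FALSE)
  }
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pos <- sort(scores[labels == 1L])
  neg <- sort(scores[labels == 0L])
  m <- length(pos)
  n <- length(neg)
  # count of scores >= t via position of t in the sorted vector
  n_pos_ge <- m - findInterval(thresholds, pos, left.open = TRUE)
  n_neg_ge <- n - findInterval(thresholds, neg, left.open = TRUE)
  structure(list(thresholds = thresholds,
                 sensitivities = n_pos_ge / m,
                 specificities = 1 - n_neg_ge / n,
                 auc = empirical_auc(pos, neg),
                 n_pos = m, n_neg = n),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("Empirical ROC curve:", length(x$thresholds), "operating points,",
      x$n_pos, "positives /", x$n_neg, "negatives\n")
  cat(sprintf("Mann-Whitney AUC: %.4f\n", x$auc))
  invisible(x)
}

#' Trapezoidal area under a ROC curve
#'
#' @param curve A [roc_curve()] object.
#' @return The trapezoidal area in ROC space (1 - specificity vs
#'   sensitivity); equals the Mann--Whitney AUC up to numerical tolerance.
#' @export
trapezoid_auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  fpr <- 1 - curve$specificities
  tpr <- curve$sensitivities
  ord <- order(fpr, tpr)
  fpr <- c(0, fpr[ord], 1)
  tpr <- c(0, tpr[ord], 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Sensitivity/specificity of the inclusive rule `score >= t` at an arbitrary
# threshold t, read off the step functions stored in the curve.
operating_point <- function(curve, t) {
  ge <- which(curve$thresholds >= t)
  i <- ge[length(ge)]  # smallest stored threshold >= t
  list(sensitivity = curve$sensitivities[i],
       specificity = curve$specificities[i])
}

# DeLong structural components (Sun & Xu fast form): per-subject placement
# values whose means are the AUC and whose covariances give its variance.
delong_placements <- function(pos_scores, neg_scores) {
  m <- length(pos_scores)
  n <- length(neg_scores)
  r_all <- rank(c(pos_scores, neg_scores), ties.method = "average")
  r_pos <- rank(pos_scores, ties.method = "average")
  r_neg <- rank(neg_scores, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(auc = (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n),
       v10 = v10, v01 = v01)
}

#' DeLong confidence interval for an empirical AUC
#'
#' Nonparametric variance estimate from DeLong's structural components with
#' a normal-approximation confidence interval, clipped to \[0, 1\]. The
#' interval is on the plain probability scale (no logit transform), matching
#' common ROC tooling defaults.
#'
#' @param pos_scores,neg_scores Scores per class, at least 2 each.
#' @param level Confidence level (default 0.95).
#' @return An object of class `"auc_estimate"`: list with `auc`, `se`,
#'   `ci_low`, `ci_high`, `level`, and `degenerate` (`TRUE`, with a warning,
#'   when all scores are tied so the variance collapses to zero).
#' @export
delong_ci <- function(pos_scores, neg_scores, level = 0.95) {
  if (length(pos_scores) < 2L || length(neg_scores) < 2L) {
    stop("need at least 2 scores per class", call. = FALSE)
  }
  if (level <= 0 || level >= 1) {
    stop("'level' must lie strictly inside (0, 1)", call. = FALSE)
  }
  pl <- delong_placements(pos_scores, neg_scores)
  v <- stats::var(pl$v10) / length(pos_scores) +
    stats::var(pl$v01) / length(neg_scores)
  degenerate <- v <= 0
  if (degenerate) {
    warning("degenerate DeLong variance (scores fully tied or perfectly ",
            "separated); se = 0", call. = FALSE)
    v <- 0
  }
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(auc = pl$auc, se = se,
                 ci_low = max(0, pl$auc - z * se),
                 ci_high = min(1, pl$auc + z * se),
                 level = level, degenerate = degenerate),
            class = "auc_estimate")
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.0f%%CI: %.3f-%.3f; DeLong se %.4f)\n",
              x$auc, 100 * x$level, x$ci_low, x$ci_high, x$se))
  invisible(x)
}

#' DeLong paired test for two correlated AUCs
#'
#' Tests equality of the empirical AUCs of two markers measured on the same
#' subjects, accounting for their correlation through the covariance of the
#' DeLong structural components. Two-sided normal test.
#'
#' @param scores_a,scores_b Marker scores on the same subjects (equal length).
#' @param labels Binary class labels shared by both markers.
#' @return A list with `auc_a`, `auc_b`, `difference`, `se`, `statistic`
#'   (z), and `p_value`. When both the difference and its variance are zero
#'   (e.g. identical score vectors) the statistic is 0 and p = 1.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("'scores_a', 'scores_b' and 'labels' must have equal length",
         call. = FALSE)
  }
  labels <- as.integer(as.logical(labels))
  if (!any(labels == 1L) || !any(labels == 0L)) {
    stop("both classes must be present in 'labels'", call. = FALSE)
  }
  pos <- labels == 1L
  pa <- delong_placements(scores_a[pos], scores_a[!pos])
  pb <- delong_placements(scores_b[pos], scores_b[!pos])
  m <- sum(pos)
  n <- sum(!pos)
  d <- pa$auc - pb$auc
  v <- (stats::var(pa$v10) + stats::var(pb$v10) -
          2 * stats::cov(pa$v10, pb$v10)) / m +
    (stats::var(pa$v01) + stats::var(pb$v01) -
       2 * stats::cov(pa$v01, pb$v01)) / n
  if (v <= 0) {
    z <- if (d == 0) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(v)
  }
  list(auc_a = pa$auc, auc_b = pb$auc, difference = d,
       se = sqrt(max(v, 0)), statistic = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Specificity-constrained cutoff selection
#'
#' Among the operating points of an empirical ROC curve whose specificity
#' strictly exceeds `min_specificity`, returns the threshold with maximal
#' sensitivity; ties are broken toward higher specificity, then toward the
#' higher threshold. If `snap_grid` is given, the selected threshold is
#' rounded up to the next grid multiple (which can only tighten the rule, so
#' the specificity constraint is preserved) and the constraint re-verified.
#'
#' @param curve A [roc_curve()] object.
#' @param min_specificity Strict lower bound on specificity (default 0.85).
#' @param snap_grid Optional grid step (e.g. 0.05 for IgMi, 25 for FKLCi)
#'   reproducing round clinical cutoffs.
#' @return A list with `threshold`, `sensitivity`, `specificity` at the
#'   returned (possibly snapped) threshold.
#' @export
select_cutoff <- function(curve, min_specificity = 0.85, snap_grid = NULL) {
  stopifnot(inherits(curve, "roc_curve"))
  feasible <- which(curve$specificities > min_specificity &
                      is.finite(curve$thresholds))
  # the Inf sentinel (flag nobody) is never a usable cutoff
  if (length(feasible) == 0L) {
    stop("no feasible cutoff: no operating point has specificity > ",
         min_specificity, call. = FALSE)
  }
  ord <- feasible[order(-curve$sensitivities[feasible],
                        -curve$specificities[feasible],
                        -curve$thresholds[feasible])]
  t_sel <- curve$thresholds[ord[1]]
  if (!is.null(snap_grid)) {
    check_positive(snap_grid, "snap_grid")
    t_sel <- ceiling(t_sel / snap_grid - 1e-9) * snap_grid
  }
  op <- operating_point(curve, t_sel)
  if (op$specificity <= min_specificity) {
    stop("selected cutoff fails the specificity constraint after snapping",
         call. = FALSE)
  }
  list(threshold = t_sel,
       sensitivity = op$sensitivity,
       specificity = op$specificity)
}

#' Spearman rank correlation between two markers
#'
#' Mid-rank Spearman correlation with an asymptotic two-sided p-value, as
#' used to quantify the association between the two indices.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return A list with `rho` and `p_value`.
#' @examples
#' rank_correlation(1:4, c(2, 1, 4, 3))  # rho = 0.6
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    stop("'x' and 'y' must have equal length", call. = FALSE)
  }
  if (length(x) < 3L) {
    stop("need at least 3 paired observations", call. = FALSE)
  }
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("rank correlation undefined for a constant vector", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
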