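#' Closed-form AUC of a binormal score model
#'
#' For scores normal in each class with a pure location shift `delta`
#' (positive class minus negative class) and class standard deviations
#' `sigma_pos`, `sigma_neg`, the probability that a random positive score
#' exceeds a random negative score is
#' \deqn{AUC = \Phi\!\left(\delta / \sqrt{\sigma_+^2 + \sigma_-^2}\right).}
#' Used to calibrate the synthetic-cohort generator to target AUCs.
#'
#' @param delta Location shift on the (log) score scale.
#' @param sigma_pos,sigma_neg Class standard deviations, strictly positive.
#' @return The AUC as a probability.
#' @examples
#' binormal_auc(0, 1, 1)       # 0.5 — no separation
#' binormal_auc(0.7826, 1, 1)  # ~0.71
#' @export
binormal_auc <- function(delta, sigma_pos = 1, sigma_neg = 1) {
  check_positive(sigma_pos, "sigma_pos")
  check_positive(sigma_neg, "sigma_neg")
  stats::pnorm(delta / sqrt(sigma_pos^2 + sigma_neg^2))
}

#' Location shift achieving a target binormal AUC
#'
#' Exact inverse of [binormal_auc()]:
#' `delta = qnorm(target_auc) * sqrt(sigma_pos^2 + sigma_neg^2)`.
#'
#' @param target_auc Desired AUC, strictly inside (0, 1).
#' @param sigma_pos,sigma_neg Class standard deviations.
#' @return The location shift `delta`.
#' @examples
#' calibrate_delta(0.71)  # ~0.7826
#' calibrate_delta(0.64)  # ~0.5070
#' @export
calibrate_delta <- function(target_auc, sigma_pos = 1, sigma_neg = 1) {
  if (!is.numeric(target_auc) || anyNA(target_auc) ||
      any(target_auc <= 0) || any(target_auc >= 1)) {
    stop("'target_auc' must lie strictly inside (0, 1)", call. = FALSE)
  }
  check_positive(sigma_pos, "sigma_pos")
  check_positive(sigma_neg, "sigma_neg")
  stats::qnorm(target_auc) * sqrt(sigma_pos^2 + sigma_neg^2)
}

#' Synthetic cohort parameters
#'
#' Bundles and validates the parameters of the log-normal cohort model used
#' by [simulate_cohort()]. Marker indices (IgMi, FKLCi) are bivariate
#' log-normal with shared within-class log-scale covariance and a pure
#' location shift `delta` for OCMB-positive patients, so each marker's
#' population AUC has the closed form of [binormal_auc()]. Defaults emulate
#' a 97-patient MS cohort at first presentation: OCMB prevalence 54/97,
#' marker AUCs 0.71 (IgMi) and 0.64 (FKLCi), moderate positive correlation
#' between the log indices, and clinically plausible magnitudes for the
#' albumin quotient and serum concentrations.
#'
#' @param n Cohort size (>= 2).
#' @param prevalence Probability of OCMB positivity, in (0, 1).
#' @param log_mu_neg Length-2 log-scale means (IgMi, FKLCi) of the
#'   OCMB-negative class. Defaults place the negative-class medians at
#'   IgMi 0.08 and FKLCi 60.
#' @param log_sigma Length-2 shared log-scale standard deviations.
#' @param delta Length-2 log-scale mean shifts for OCMB-positive patients.
#'   Default `NULL` calibrates the shifts to `target_auc` via
#'   [calibrate_delta()].
#' @param target_auc Length-2 marker AUCs used when `delta` is `NULL`.
#' @param rho Latent correlation between log-IgMi and log-FKLCi, in (-1, 1).
#' @param qalb_log_mu,qalb_log_sigma Log-normal parameters of the albumin
#'   quotient (default median 0.005).
#' @param serum_log_mu,serum_log_sigma Length-3 log-normal parameters of the
#'   serum concentrations (IgM, FKLC, albumin) in mg/L; default medians
#'   1000, 15 and 42000.
#' @param activity_prob Probability of the disease-activity flag (set to
#'   `NA` to omit the column). Default 81/97.
#' @param fixed_counts If `TRUE`, the positive count is fixed at
#'   `round(n * prevalence)` instead of Bernoulli-random.
#' @return A validated list of class `"cohort_params"`.
#' @export
cohort_params <- function(n = 97,
                          prevalence = 54 / 97,
                          log_mu_neg = log(c(igmi = 0.08, fklci = 60)),
                          log_sigma = c(1, 1),
                          delta = NULL,
                          target_auc = c(0.71, 0.64),
                          rho = 0.5,
                          qalb_log_mu = log(0.005),
                          qalb_log_sigma = 0.3,
                          serum_log_mu = log(c(igm = 1000, fklc = 15,
                                               albumin = 42000)),
                          serum_log_sigma = c(0.25, 0.25, 0.25),
                          activity_prob = 81 / 97,
                          fixed_counts = FALSE) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n)) {
    stop("'n' must be a single integer >= 2", call. = FALSE)
  }
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      prevalence <= 0 || prevalence >= 1) {
    stop("'prevalence' must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!is.numeric(rho) || length(rho) != 1L || rho <= -1 || rho >= 1) {
    stop("'rho' must lie strictly inside (-1, 1)", call. = FALSE)
  }
  if (length(log_mu_neg) != 2L || length(log_sigma) != 2L) {
    stop("'log_mu_neg' and 'log_sigma' must have length 2", call. = FALSE)
  }
  check_positive(log_sigma, "log_sigma")
  check_positive(qalb_log_sigma, "qalb_log_sigma")
  check_positive(serum_log_sigma, "serum_log_sigma")
  if (length(serum_log_mu) != 3L || length(serum_log_sigma) != 3L) {
    stop("'serum_log_mu' and 'serum_log_sigma' must have length 3",
         call. = FALSE)
  }
  if (is.null(delta)) {
    if (length(target_auc) != 2L) {
      stop("'target_auc' must have length 2", call. = FALSE)
    }
    delta <- calibrate_delta(target_auc, log_sigma, log_sigma)
  }
  if (length(delta) != 2L || anyNA(delta)) {
    stop("'delta' must be a length-2 numeric vector", call. = FALSE)
  }
  structure(list(n = as.integer(n), prevalence = prevalence,
                 log_mu_neg = unname(log_mu_neg),
                 log_sigma = unname(log_sigma),
                 delta = unname(delta), rho = rho,
                 qalb_log_mu = qalb_log_mu, qalb_log_sigma = qalb_log_sigma,
                 serum_log_mu = unname(serum_log_mu),
                 serum_log_sigma = unname(serum_log_sigma),
                 activity_prob = activity_prob,
                 fixed_counts = isTRUE(fixed_counts)),
            class = "cohort_params")
}

#' Reconstruct concentrations from indices
#'
#' Inverse of the index computation: given the three dimensionless ratios
#' and the serum concentrations, back-computes the CSF concentrations so that
#' [compute_panel()] recovers the ratios exactly:
#' `csf_albumin = qalb * serum_albumin`, `csf_igm = igmi * qalb * serum_igm`,
#' `csf_fklc = fklci * qalb * serum_fklc`.
#'
#' @param igmi,fklci,qalb Dimensionless indices, strictly positive.
#' @param serum_igm,serum_fklc,serum_albumin Serum concentrations (mg/L).
#' @return A data frame of the six concentrations; vectorized.
#' @examples
#' backfill_concentrations(0.2, 25, 0.005, 1000, 10, 40000)
#' @export
backfill_concentrations <- function(igmi, fklci, qalb,
                                    serum_igm, serum_fklc, serum_albumin) {
  check_positive(igmi, "igmi")
  check_positive(fklci, "fklci")
  check_positive(qalb, "qalb")
  check_positive(serum_igm, "serum_igm")
  check_positive(serum_fklc, "serum_fklc")
  check_positive(serum_albumin, "serum_albumin")
  data.frame(csf_igm = igmi * qalb * serum_igm,
             serum_igm = serum_igm,
             csf_fklc = fklci * qalb * serum_fklc,
             serum_fklc = serum_fklc,
             csf_albumin = qalb * serum_albumin,
             serum_albumin = serum_albumin)
}

#' Simulate a synthetic cohort
#'
#' Draws a cohort of paired CSF/serum samples under the log-normal model of
#' [cohort_params()]: OCMB status Bernoulli (or fixed-count), log indices
#' bivariate normal with correlation `rho` and a class location shift,
#' albumin quotient and serum concentrations independent log-normal, CSF
#' concentrations back-filled so the derived indices equal the drawn ones.
#' Deterministic given `seed`.
#'
#' @param params A [cohort_params()] object (default: the package defaults).
#' @param seed Integer random seed (required for reproducibility).
#' @return A cohort data frame with `patient_id`, the six concentrations,
#'   `ocmb_status`, `activity` (if modelled), plus the generating `qalb`,
#'   `igmi`, `fklci` columns.
#' @examples
#' cohort <- simulate_cohort(cohort_params(n = 20), seed = 1)
#' @export
simulate_cohort <- function(params = cohort_params(), seed) {
  if (!inherits(params, "cohort_params")) {
    stop("'params' must be created by cohort_params()", call. = FALSE)
  }
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  n <- params$n
  status <- if (params$fixed_counts) {
    n_pos <- round(n * params$prevalence)
    sample(rep(c(1L, 0L), c(n_pos, n - n_pos)))
  } else {
    stats::rbinom(n, 1L, params$prevalence)
  }
  # Correlated log indices: z2 = rho*z1 + sqrt(1-rho^2)*e
  z1 <- stats::rnorm(n)
  z2 <- params$rho * z1 + sqrt(1 - params$rho^2) * stats::rnorm(n)
  log_igmi <- params$log_mu_neg[1] + status * params$delta[1] +
    params$log_sigma[1] * z1
  log_fklci <- params$log_mu_neg[2] + status * params$delta[2] +
    params$log_sigma[2] * z2
  qalb <- stats::rlnorm(n, params$qalb_log_mu, params$qalb_log_sigma)
  serum_igm <- stats::rlnorm(n, params$serum_log_mu[1],
                             params$serum_log_sigma[1])
  serum_fklc <- stats::rlnorm(n, params$serum_log_mu[2],
                              params$serum_log_sigma[2])
  serum_albumin <- stats::rlnorm(n, params$serum_log_mu[3],
                                 params$serum_log_sigma[3])
  conc <- backfill_concentrations(exp(log_igmi), exp(log_fklci), qalb,
                                  serum_igm, serum_fklc, serum_albumin)
  cohort <- cbind(data.frame(patient_id = sprintf("P%03d", seq_len(n))),
                  conc)
  cohort$ocmb_status <- status
  if (!is.na(params$activity_prob)) {
    cohort$activity <- stats::rbinom(n, 1L, params$activity_prob)
  }
  cohort$qalb <- qalb
  cohort$igmi <- exp(log_igmi)
  cohort$fklci <- exp(log_fklci)
  cohort
}
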