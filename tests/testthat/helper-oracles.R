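# Independent oracles and shared fixtures.

# Brute-force Mann-Whitney AUC: explicit loop over all (pos, neg) pairs.
brute_force_auc <- function(pos, neg) {
  total <- 0
  for (x in pos) {
    for (y in neg) {
      total <- total + if (x > y) 1 else if (x == y) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Brute-force constrained cutoff selection: enumerate every candidate
# threshold (all observed scores), apply the inclusive rule score >= t,
# keep those with specificity strictly above the floor, rank by the
# documented tie-breaks.
brute_force_cutoff <- function(pos, neg, min_spec) {
  candidates <- sort(unique(c(pos, neg)), decreasing = TRUE)
  best <- NULL
  for (t in candidates) {
    sens <- mean(pos >= t)
    spec <- mean(neg < t)
    if (spec <= min_spec) next
    if (is.null(best) ||
        sens > best$sens ||
        (sens == best$sens && spec > best$spec) ||
        (sens == best$sens && spec == best$spec && t > best$t)) {
      best <- list(t = t, sens = sens, spec = spec)
    }
  }
  best
}

# A small random labeled panel with ties possible (scores on a coarse grid).
random_panel <- function(n = 40, seed) {
  set.seed(seed)
  status <- rbinom(n, 1, 0.5)
  if (all(status == 0)) status[1] <- 1
  if (all(status == 1)) status[1] <- 0
  data.frame(
    igmi = round(exp(rnorm(n, -2.5 + 0.6 * status, 0.9)), 2),
    fklci = round(exp(rnorm(n, 4.1 + 0.5 * status, 0.9))),
    ocmb_status = status
  )
}

# Published-style diagnostic table used as a frozen fixture (printed
# integer percentages): four single-marker rows and four OR models.
published_grid <- function() {
  data.frame(
    name = c("IgMi 0.2", "IgMi 0.3", "FKLCi 200", "FKLCi 250",
             "A", "B", "C", "D"),
    type = c(rep("single", 4), rep("model", 4)),
    igmi_cutoff = c(0.2, 0.3, NA, NA, 0.2, 0.3, 0.2, 0.3),
    fklci_cutoff = c(NA, NA, 200, 250, 200, 250, 250, 200),
    specificity = c(93, 93, 88, 93, 86, 90, 90, 86),
    sensitivity = c(42, 27, 20, 18, 53, 38, 51, 40),
    ppv = c(88, 83, 69, 77, 83, 84, 88, 79),
    npv = c(55, 49, 46, 46, 58, 53, 54, 70),
    prom = c(27, 19, 16, 13, 36, 26, 33, 28),
    stringsAsFactors = FALSE
  )
}

# Reference sample used across the index tests.
reference_sample <- function() {
  data.frame(patient_id = "P1",
             csf_igm = 1, serum_igm = 1000,
             csf_fklc = 1.25, serum_fklc = 10,
             csf_albumin = 200, serum_albumin = 40000,
             ocmb_status = 1)
}
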