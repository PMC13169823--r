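test_that("the OR rule uses inclusive comparisons on both markers", {
  model_c <- decision_model(0.2, 250, name = "C")
  expect_true(apply_rule(data.frame(igmi = 0.25, fklci = 100), model_c))
  expect_true(apply_rule(data.frame(igmi = 0.2, fklci = 249.999), model_c))
  expect_true(apply_rule(data.frame(igmi = 0.05, fklci = 250), model_c))
  expect_false(apply_rule(data.frame(igmi = 0.19, fklci = 249), model_c))
  expect_error(decision_model(0, 250), "igmi_cutoff")
  expect_error(apply_rule(data.frame(igmi = 1), model_c), "fklci")
})

test_that("confusion counts partition the cohort", {
  panel <- data.frame(
    patient_id = c("tp", "fp", "fn", "tn"),
    igmi = c(0.5, 0.5, 0.1, 0.1),
    fklci = c(100, 100, 100, 100),
    ocmb_status = c(1, 0, 1, 0)
  )
  counts <- confusion_counts(panel, decision_model(0.2, 250))
  expect_equal(unclass(counts)[c("tp", "fp", "fn", "tn")],
               list(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  # degenerate rule above every observed value
  none <- confusion_counts(panel, decision_model(10, 1e6))
  expect_equal(none$tp + none$fp, 0)
  expect_equal(none$fn, 2)
  expect_equal(none$tn, 2)
  panel$ocmb_status[2] <- NA
  expect_error(confusion_counts(panel, decision_model(0.2, 250)), "fp")
})

test_that("Clopper-Pearson intervals match the binom.test oracle", {
  set.seed(70)
  for (i in 1:30) {
    n <- sample(5:120, 1)
    x <- sample(0:n, 1)
    ours <- proportion_ci(x, n)
    ref <- binom.test(x, n)$conf.int
    expect_equal(unname(ours), as.numeric(ref), tolerance = 1e-12)
  }
  # closed forms at the boundary
  ci <- proportion_ci(43, 43)
  expect_equal(unname(ci["high"]), 1)
  expect_equal(unname(ci["low"]), 0.025^(1 / 43))
  expect_equal(unname(proportion_ci(0, 10)["low"]), 0)
  # published-style row: 40/43 ~ 93 % (81-99)
  ci <- proportion_ci(40, 43)
  expect_equal(round(100 * 40 / 43), 93)
  expect_equal(round(100 * ci["low"]), 81, ignore_attr = TRUE)
  expect_equal(round(100 * ci["high"]), 99, ignore_attr = TRUE)
  expect_error(proportion_ci(5, 4), "successes")
  expect_error(proportion_ci(1, 4, level = 1), "level")
})

test_that("Wilson intervals are a sane alternative", {
  cp <- proportion_ci(40, 43)
  wi <- proportion_ci(40, 43, method = "wilson")
  expect_true(wi["low"] > cp["low"])      # Wilson is narrower here
  expect_true(wi["low"] < 40 / 43 && wi["high"] > 40 / 43)
  expect_equal(unname(proportion_ci(0, 10, method = "wilson")["low"]), 0)
})

test_that("diagnostic reports satisfy the defining identities", {
  sym <- diagnostics(structure(list(tp = 1L, fp = 1L, fn = 1L, tn = 1L),
                               class = "confusion_counts"))
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    expect_equal(sym[[m]]$estimate, 0.5)
  }
  expect_equal(sym$prom, 0.5)
  # PROM on a 97-patient cohort with 32 flagged
  rep32 <- diagnostics(structure(list(tp = 28L, fp = 4L, fn = 26L, tn = 39L),
                                 class = "confusion_counts"))
  expect_equal(rep32$prom, 32 / 97)
  expect_equal(round(100 * rep32$prom), 33)
  # undefined PPV when nothing is flagged
  none <- diagnostics(structure(list(tp = 0L, fp = 0L, fn = 3L, tn = 5L),
                                class = "confusion_counts"))
  expect_true(is.na(none$ppv$estimate))
  expect_identical(none$undefined, "ppv")
  expect_equal(none$prom, 0)
  # all flagged
  all_f <- diagnostics(structure(list(tp = 5L, fp = 3L, fn = 0L, tn = 0L),
                                 class = "confusion_counts"))
  expect_equal(all_f$prom, 1)
  # Bayes and PROM identities on random counts
  set.seed(71)
  for (i in 1:20) {
    k <- as.list(rmultinom(1, 60, c(0.3, 0.15, 0.25, 0.3))[, 1] + 1L)
    names(k) <- c("tp", "fp", "fn", "tn")
    r <- diagnostics(structure(k, class = "confusion_counts"))
    prev <- r$prevalence
    sens <- r$sensitivity$estimate
    spec <- r$specificity$estimate
    expect_equal(r$ppv$estimate,
                 sens * prev / (sens * prev + (1 - spec) * (1 - prev)))
    expect_equal(r$prom, sens * prev + (1 - spec) * (1 - prev))
  }
})

test_that("grid evaluation obeys OR-dominance and cutoff monotonicity", {
  for (seed in c(81, 82, 83)) {
    panel <- random_panel(n = 60, seed = seed)
    igmi_cuts <- unname(quantile(panel$igmi, c(0.5, 0.8)))
    fklci_cuts <- unname(quantile(panel$fklci, c(0.5, 0.8)))
    models <- list(
      decision_model(igmi_cuts[1], fklci_cuts[1], name = "A"),
      decision_model(igmi_cuts[2], fklci_cuts[2], name = "B"),
      decision_model(igmi_cuts[1], fklci_cuts[2], name = "C"),
      decision_model(igmi_cuts[2], fklci_cuts[1], name = "D")
    )
    grid <- evaluate_grid(panel, models, igmi_cutoffs = igmi_cuts,
                          fklci_cutoffs = fklci_cuts)
    expect_equal(nrow(grid), 8)
    expect_equal(grid$tp + grid$fp + grid$fn + grid$tn, rep(60L, 8))
    single <- function(type, cutoff) {
      grid[grid$type == type & grid[[paste0(tolower(type), "_cutoff")]] ==
             cutoff, ]
    }
    for (m in models) {
      row <- grid[grid$name == m$name, ]
      si <- single("IgMi", m$igmi_cutoff)
      sf <- single("FKLCi", m$fklci_cutoff)
      expect_gte(row$sensitivity, max(si$sensitivity, sf$sensitivity))
      expect_lte(row$specificity, min(si$specificity, sf$specificity))
      expect_gte(row$prom, max(si$prom, sf$prom))
    }
    # raising a cutoff shrinks the flagged set
    lo <- grid[grid$name == "A", ]
    hi <- grid[grid$name == "B", ]
    expect_lte(hi$sensitivity, lo$sensitivity)
    expect_lte(hi$prom, lo$prom)
    expect_gte(hi$specificity, lo$specificity)
  }
  expect_error(evaluate_grid(random_panel(10, 1), list()), "nothing")
})

test_that("optimal-model selection is lexicographic with a name tie-break", {
  grid <- published_grid()
  best <- select_optimal(grid)
  expect_equal(best$name, "C")  # B ties on specificity, C wins on PPV
  # single-model table
  one <- grid[grid$name == "D", ]
  expect_equal(select_optimal(one)$name, "D")
  # exact metric tie falls back to the name
  tied <- grid[grid$name %in% c("B", "C"), ]
  tied$specificity <- 90; tied$ppv <- 88; tied$prom <- 33
  expect_equal(select_optimal(tied)$name, "B")
  expect_error(select_optimal(grid[0, ]), "non-empty")
  expect_error(select_optimal(grid[grid$type == "single", ]), "no two-marker")
})
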