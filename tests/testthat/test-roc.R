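test_that("empirical AUC matches pairwise counting, including ties", {
  expect_equal(empirical_auc(c(2, 3), 1), 1)
  expect_equal(empirical_auc(c(1, 2), c(1, 3)), 0.375)  # (0.5+0+1+0)/4
  expect_equal(empirical_auc(c(4, 7, 9), c(4, 7, 9)), 0.5)
  set.seed(10)
  for (i in 1:30) {
    pos <- sample(0:8, sample(1:12, 1), replace = TRUE)
    neg <- sample(0:8, sample(1:12, 1), replace = TRUE)
    expect_equal(empirical_auc(pos, neg), brute_force_auc(pos, neg))
    # complement property
    expect_equal(empirical_auc(pos, neg) + empirical_auc(neg, pos), 1)
  }
  expect_error(empirical_auc(numeric(), 1), "at least one")
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(20)
  pos <- rnorm(15, 1)
  neg <- rnorm(12)
  base <- empirical_auc(pos, neg)
  for (f in list(exp, function(x) x^3, function(x) 5 * x - 2,
                 function(x) atan(x))) {
    expect_equal(empirical_auc(f(pos), f(neg)), base)
  }
})

test_that("ROC curves are monotone, anchored, and integrate to the AUC", {
  curve <- roc_curve(1:4, c(0, 0, 1, 1))
  expect_equal(curve$auc, 1)
  expect_true(any(curve$sensitivities == 1 & curve$specificities == 1))
  set.seed(30)
  for (i in 1:20) {
    n <- sample(6:40, 1)
    scores <- round(rnorm(n), 1)  # coarse grid forces ties
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) %in% c(0, n)) next
    curve <- roc_curve(scores, labels)
    expect_true(all(diff(curve$sensitivities) >= 0))
    expect_true(all(diff(curve$specificities) <= 0))
    expect_equal(curve$sensitivities[1], 0)            # Inf sentinel
    expect_equal(curve$specificities[1], 1)
    expect_equal(curve$sensitivities[length(curve$thresholds)], 1)
    expect_equal(trapezoid_auc(curve), curve$auc, tolerance = 1e-12)
  }
  expect_error(roc_curve(1:3, c(1, 1, 1)), "both classes")
  expect_error(roc_curve(1:3, c(0, 1)), "equal length")
})

test_that("label shuffling yields chance-level AUC on average", {
  set.seed(31)
  scores <- rnorm(60)
  aucs <- replicate(400, {
    labels <- sample(rep(c(0, 1), each = 30))
    roc_curve(scores, labels)$auc
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.02)
})

test_that("DeLong AUC variance agrees with pROC", {
  set.seed(40)
  for (i in 1:10) {
    pos <- rnorm(25, 0.8)
    neg <- rnorm(20)
    est <- delong_ci(pos, neg)
    ref <- pROC::roc(controls = neg, cases = pos, quiet = TRUE,
                     direction = "<")
    expect_equal(est$auc, as.numeric(pROC::auc(ref)))
    expect_equal(est$se^2, as.numeric(pROC::var(ref, method = "delong")),
                 tolerance = 1e-12)
    ref_ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
    expect_equal(est$ci_low, max(0, ref_ci[1]), tolerance = 1e-9)
    expect_equal(est$ci_high, min(1, ref_ci[3]), tolerance = 1e-9)
  }
})

test_that("DeLong interval behaves at the boundaries", {
  expect_warning(est <- delong_ci(rnorm(60, 20), rnorm(60)), "degenerate")
  expect_equal(est$auc, 1)
  expect_equal(est$ci_high, 1)
  expect_warning(deg <- delong_ci(rep(1, 5), rep(1, 5)), "degenerate")
  expect_equal(deg$se, 0)
  expect_true(deg$degenerate)
  # doubling every observation keeps the AUC, shrinks the se
  set.seed(41)
  pos <- rnorm(20, 0.5)
  neg <- rnorm(20)
  one <- delong_ci(pos, neg)
  two <- delong_ci(rep(pos, 2), rep(neg, 2))
  expect_equal(two$auc, one$auc)
  expect_lt(two$se, one$se)
})

test_that("DeLong interval coverage is near nominal in binormal data", {
  true_auc <- binormal_auc(0.7826, 1, 1)
  set.seed(42)
  covered <- replicate(2000, {
    est <- delong_ci(rnorm(54, 0.7826), rnorm(43))
    est$ci_low <= true_auc && true_auc <= est$ci_high
  })
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.97)
})

test_that("paired DeLong test agrees with pROC and is antisymmetric", {
  set.seed(50)
  for (i in 1:10) {
    n <- 60
    labels <- rep(c(0, 1), each = n / 2)
    z <- rnorm(n)
    a <- z + rnorm(n, 0.4 * labels)
    b <- 0.7 * z + rnorm(n, 0.3 * labels)
    ours <- delong_test(a, b, labels)
    ref <- pROC::roc.test(
      pROC::roc(labels, a, quiet = TRUE, direction = "<"),
      pROC::roc(labels, b, quiet = TRUE, direction = "<"),
      method = "delong", paired = TRUE
    )
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
    flipped <- delong_test(b, a, labels)
    expect_equal(flipped$statistic, -ours$statistic)
    expect_equal(flipped$p_value, ours$p_value)
  }
  same <- delong_test(1:10, 1:10, rep(c(0, 1), 5))
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)
  expect_error(delong_test(1:4, 1:5, rep(0:1, 2)), "equal length")
})

test_that("cutoff selection matches brute-force enumeration", {
  neg <- 1:20
  pos <- 15:34
  curve <- roc_curve(c(pos, neg), rep(c(1, 0), each = 20))
  sel <- select_cutoff(curve, min_specificity = 0.85)
  oracle <- brute_force_cutoff(pos, neg, 0.85)
  expect_equal(sel$threshold, oracle$t)
  expect_equal(sel$sensitivity, oracle$sens)
  expect_equal(sel$specificity, oracle$spec)
  # frozen oracle values for this fixture
  expect_equal(sel$threshold, 19)
  expect_equal(sel$sensitivity, 16 / 20)
  expect_equal(sel$specificity, 18 / 20)
  # randomized agreement with the enumeration oracle
  set.seed(60)
  for (i in 1:25) {
    p <- sample(1:40, 15, replace = TRUE)
    n <- sample(1:30, 12, replace = TRUE)
    curve <- roc_curve(c(p, n), rep(c(1, 0), c(15, 12)))
    oracle <- brute_force_cutoff(p, n, 0.8)
    if (is.null(oracle)) {
      expect_error(select_cutoff(curve, 0.8), "no feasible")
    } else {
      sel <- select_cutoff(curve, 0.8)
      expect_equal(sel$threshold, oracle$t)
      expect_gt(sel$specificity, 0.8)  # post-hoc constraint check
    }
  }
})

test_that("perfect separation returns the smallest positive score", {
  curve <- roc_curve(c(5, 6, 1, 2), c(1, 1, 0, 0))
  sel <- select_cutoff(curve, min_specificity = 0.85)
  expect_equal(sel$threshold, 5)  # highest threshold with sens 1, spec 1
  expect_equal(sel$sensitivity, 1)
  expect_equal(sel$specificity, 1)
})

test_that("grid snapping rounds cutoffs up and keeps the constraint", {
  set.seed(61)
  neg <- exp(rnorm(40, -3, 0.7))
  pos <- exp(rnorm(40, -1.5, 0.7))
  curve <- roc_curve(c(pos, neg), rep(c(1, 0), each = 40))
  raw <- select_cutoff(curve, 0.85)
  snapped <- select_cutoff(curve, 0.85, snap_grid = 0.05)
  expect_equal(snapped$threshold, ceiling(raw$threshold / 0.05 - 1e-9) * 0.05)
  expect_gt(snapped$specificity, 0.85)
  # an exact grid multiple must not be pushed a step further
  curve2 <- roc_curve(c(0.2, 0.3, 0.05, 0.1), c(1, 1, 0, 0))
  expect_equal(select_cutoff(curve2, 0.85, snap_grid = 0.05)$threshold, 0.2)
  expect_error(select_cutoff(curve2, 1), "no feasible")
})

test_that("rank correlation reproduces the Spearman formula", {
  expect_equal(rank_correlation(1:10, 1:10)$rho, 1)
  expect_equal(rank_correlation(1:10, 10:1)$rho, -1)
  # 1 - 6*sum(d^2)/(n(n^2-1)) with d^2 = 4
  expect_equal(rank_correlation(1:4, c(2, 1, 4, 3))$rho, 0.6)
  expect_error(rank_correlation(c(1, 1, 1), 1:3), "constant")
  expect_error(rank_correlation(1:2, 1:2), "at least 3")
  expect_error(rank_correlation(1:3, 1:4), "equal length")
})
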