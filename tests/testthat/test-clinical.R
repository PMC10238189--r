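test_that("perfect separation and degenerate groups give the expected thresholds", {
  thr <- univariate_threshold(c(10, 20, 30), c(0, 0, 1))
  expect_equal(thr, 5.5)
  met <- sensitivity_specificity(c(c(10, 20, 30) > thr, c(0, 0, 1) > thr),
                                 rep(c("case", "control"), each = 3))
  expect_equal(met$sensitivity, 100)
  expect_equal(met$specificity, 100)
  # identical groups: J = 0 achieved at +Inf (call nothing positive)
  expect_equal(univariate_threshold(c(1, 2, 3), c(1, 2, 3)), Inf)
  expect_error(univariate_threshold(numeric(0), 1), class = "dmspr_domain_error")
})

test_that("the returned threshold attains the brute-force maximum of TPR - FPR", {
  brute_best_j <- function(cases, controls) {
    cand <- c(-Inf, sort(unique(c(cases, controls))), Inf)
    max(vapply(cand, function(t) mean(cases > t) - mean(controls > t),
               numeric(1)))
  }
  withr::with_seed(61, {
    for (i in 1:200) {
      cases <- round(rpois(15, 5) + rnorm(15, 2), 2)
      controls <- round(rpois(15, 3) + rnorm(15), 2)
      thr <- univariate_threshold(cases, controls)
      j <- mean(cases > thr) - mean(controls > thr)
      expect_equal(j, brute_best_j(cases, controls), tolerance = 1e-12)
    }
  })
})

test_that("printed clinical percentages are reproduced from the cohort counts", {
  as_calls <- function(pos_case, n_case, pos_ctrl, n_ctrl) {
    list(calls = c(rep(c(TRUE, FALSE), c(pos_case, n_case - pos_case)),
                   rep(c(TRUE, FALSE), c(pos_ctrl, n_ctrl - pos_ctrl))),
         labels = rep(c("case", "control"), c(n_case, n_ctrl)))
  }
  counts <- list(c(25, 88), c(21, 85), c(22, 100), c(22, 85), c(35, 82))
  ctrl_pos <- c(4, 5, 0, 5, 6)
  sens_pct <- c(64, 54, 56, 56, 90)
  for (i in seq_along(counts)) {
    cc <- as_calls(counts[[i]][1], 39, ctrl_pos[i], 33)
    met <- sensitivity_specificity(cc$calls, cc$labels)
    expect_equal(met$sensitivity_pct, sens_pct[i])
    expect_equal(met$specificity_pct, counts[[i]][2])
  }
  # exact values behind the 4-marker panel row: 35/39 and 27/33
  met <- sensitivity_specificity(as_calls(35, 39, 6, 33)$calls,
                                 rep(c("case", "control"), c(39, 33)))
  expect_equal(met$sensitivity, 35 / 39 * 100, tolerance = 1e-12)
  expect_equal(met$specificity, 27 / 33 * 100, tolerance = 1e-12)
  expect_error(sensitivity_specificity(TRUE, "case"),
               class = "dmspr_undefined_metric_error")
})

test_that("full-data IRLS coefficients match glm to 1e-6", {
  cohort <- simulate_cohort(60, 60, seed = 62)
  markers <- c("SOX17", "CDO1", "TAC1", "HOXA7")
  fit <- fit_panel_logistic(cohort, markers)
  g <- glm(I(label == "case") ~ SOX17 + CDO1 + TAC1 + HOXA7,
           data = cohort, family = binomial)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$coefficients - coef(g))), 1e-6)
})

test_that("LOOCV separates a separable cohort and is honest on null data", {
  sep <- simulate_cohort(15, 15, tibble::tibble(marker = "M1", case_rate = 500,
                                                control_rate = 0), seed = 63)
  probs <- loocv_logistic(sep, "M1")
  expect_true(all(probs$prob[probs$label == "case"] > 0.5))
  expect_true(all(probs$prob[probs$label == "control"] < 0.5))
  # label permutation: held-out AUC hovers at chance
  null <- simulate_cohort(100, 100,
                          tibble::tibble(marker = c("M1", "M2"),
                                         case_rate = c(5, 8),
                                         control_rate = c(5, 8)), seed = 64)
  auc <- roc_auc(loocv_logistic(null, c("M1", "M2"))$prob, null$label)$auc
  expect_gt(auc, 0.35)
  expect_lt(auc, 0.65)
  # constant features are dropped with a warning, not fatal
  cst <- simulate_cohort(10, 10, seed = 65)
  cst$flat <- 1
  expect_warning(fit_panel_logistic(cst, c("SOX17", "flat")), "constant")
})

test_that("trapezoidal AUC equals the Mann-Whitney rank statistic with ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1),
                       c("case", "case", "control", "control"))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c("case", "control"), 5))$auc, 0.5)
  mw_auc <- function(p, is_case) {
    r <- rank(p); n1 <- sum(is_case); n0 <- sum(!is_case)
    (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  withr::with_seed(66, {
    for (i in 1:500) {
      n1 <- sample(3:15, 1); n0 <- sample(3:15, 1)
      p <- round(runif(n1 + n0), sample(1:2, 1))  # coarse rounding forces ties
      lab <- rep(c(TRUE, FALSE), c(n1, n0))
      r <- roc_auc(p, lab)
      expect_equal(r$auc, mw_auc(p, lab), tolerance = 1e-12)
      # ROC is a monotone step curve from (0,0) to (1,1)
      expect_true(all(diff(r$roc$fpr) >= 0))
      expect_true(all(diff(r$roc$tpr) >= 0))
      expect_equal(c(r$roc$fpr[1], r$roc$tpr[1]), c(0, 0))
      expect_equal(c(dplyr::last(r$roc$fpr), dplyr::last(r$roc$tpr)), c(1, 1))
    }
  })
  expect_error(roc_auc(c(0.1, 0.9), c("case", "case")),
               class = "dmspr_undefined_metric_error")
})

test_that("AUC agrees with pROC on a non-trivial cohort", {
  skip_if_not_installed("pROC")
  cohort <- simulate_cohort(39, 33, seed = 67)
  probs <- loocv_logistic(cohort, c("SOX17", "CDO1", "TAC1", "HOXA7"))
  ours <- roc_auc(probs$prob, probs$label)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = probs$label, predictor = probs$prob,
    levels = c("control", "case"), direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("AUC is invariant under strictly monotone transforms of the score", {
  withr::with_seed(68, {
    p <- runif(40); lab <- rep(c(TRUE, FALSE), 20)
  })
  a0 <- roc_auc(p, lab)$auc
  expect_equal(roc_auc(qlogis(p), lab)$auc, a0)
  expect_equal(roc_auc(p^3, lab)$auc, a0)
})

test_that("stratified bootstrap CIs are deterministic under a seed and sane", {
  probs <- c(rep(0.9, 10), rep(0.1, 10))
  labs <- rep(c("case", "control"), each = 10)
  ci <- bootstrap_auc_ci(probs, labs, n_boot = 200, seed = 69)
  expect_equal(ci$ci_low, 1)
  expect_equal(ci$ci_high, 1)
  cohort <- simulate_cohort(39, 33, seed = 70)
  pr <- loocv_logistic(cohort, c("SOX17", "CDO1"))
  ci1 <- bootstrap_auc_ci(pr$prob, pr$label, n_boot = 300, seed = 71)
  ci2 <- bootstrap_auc_ci(pr$prob, pr$label, n_boot = 300, seed = 71)
  expect_identical(ci1, ci2)
  expect_lte(ci1$ci_low, ci1$auc)
  expect_gte(ci1$ci_high, ci1$auc)
  expect_error(bootstrap_auc_ci(pr$prob, pr$label, n_boot = 50),
               class = "dmspr_domain_error")
})

test_that("bootstrap intervals cover a known population AUC at near-nominal rate", {
  # binormal scores with population AUC 0.8
  target <- 0.8
  delta <- sqrt(2) * qnorm(target)
  withr::with_seed(72, {
    covered <- replicate(200, {
      p <- c(rnorm(40, delta), rnorm(40))
      ci <- bootstrap_auc_ci(p, rep(c("case", "control"), each = 40),
                             n_boot = 300)
      ci$ci_low <= target && target <= ci$ci_high
    })
  })
  expect_gte(mean(covered), 0.88)
})

test_that("panel search ranks informative markers first and enumerates subsets", {
  cohort <- simulate_cohort(30, 30,
                            tibble::tibble(marker = c("GOOD", "NOISE"),
                                           case_rate = c(50, 5),
                                           control_rate = c(2, 5)), seed = 73)
  res <- panel_search(cohort, c("GOOD", "NOISE"))
  expect_equal(nrow(res), 3)
  singles <- res[res$n_markers == 1, ]
  expect_gt(singles$auc[singles$markers == "GOOD"],
            singles$auc[singles$markers == "NOISE"])
  four <- simulate_cohort(20, 20, seed = 74)
  expect_equal(nrow(panel_search(four, c("SOX17", "CDO1", "TAC1", "HOXA7"))), 15)
  expect_error(panel_search(four, paste0("m", 1:9)),
               class = "dmspr_combinatorial_limit_error")
})

test_that("evaluate_panel assembles a coherent result object", {
  cohort <- simulate_cohort(39, 33, seed = 75)
  pe <- evaluate_panel(cohort, c("SOX17", "CDO1", "TAC1", "HOXA7"),
                       n_boot = 200, seed = 76)
  expect_s3_class(pe, "panel_eval")
  expect_true(pe$auc_ci_low <= pe$auc && pe$auc <= pe$auc_ci_high)
  g <- glance(pe)
  expect_equal(g$n_case, 39)
  expect_equal(g$n_control, 33)
  expect_equal(nrow(tidy(pe)), 4)
  expect_s3_class(autoplot(pe), "ggplot")
})
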