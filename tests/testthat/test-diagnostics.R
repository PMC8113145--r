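test_that("mann_whitney matches exact enumeration and degenerate rules", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)            # no pair with x above y
  expect_equal(mw$p, 0.1)          # 2 of the 20 equally likely orderings
  expect_equal(mann_whitney(c(2, 2, 2), c(2, 2))$p, 1)
  same <- mann_whitney(c(1, 5, 9, 12), c(1, 5, 9, 12))
  expect_equal(same$p, 1, tolerance = 0.05)
  expect_equal(same$U, 8)          # n1*n2/2 by symmetry
  set.seed(31)
  big <- mann_whitney(rnorm(500, 1), rnorm(500))
  expect_lt(big$p, 1e-10)
})

test_that("roc_auc handles perfect, null and degenerate inputs", {
  perf <- roc_auc(c(5, 6, 7, 1, 2), rep(c("TP", "TRC"), c(3, 2)), "higher")
  expect_equal(perf$auc$auc, 1)
  set.seed(32)
  null <- roc_auc(rnorm(4000), rep(c("TP", "TRC"), 2000), "higher")
  expect_equal(null$auc$auc, 0.5, tolerance = 0.03)
  expect_gt(null$auc$p, 0.001)
  expect_error(roc_auc(1:5, rep("TP", 5), "higher"), "both classes")
})

test_that("trapezoid AUC equals the midrank U statistic on random instances", {
  set.seed(33)
  for (i in 1:25) {
    inst <- random_roc_instance(sample(3:40, 1), sample(3:40, 1),
                                ties = i %% 2 == 0)
    n1 <- sum(inst$labels == "TP"); n0 <- sum(inst$labels == "TRC")
    auc <- roc_auc(inst$scores, inst$labels, "higher")$auc$auc
    expect_equal(auc, u_midrank(inst$scores, inst$labels) / (n1 * n0),
                 tolerance = 1e-12)
  }
})

test_that("direction handling: higher on scores equals lower on negated scores", {
  set.seed(34)
  inst <- random_roc_instance(25, 15)
  hi <- roc_auc(inst$scores, inst$labels, "higher")
  lo <- roc_auc(-inst$scores, inst$labels, "lower")
  expect_equal(hi$auc$auc, lo$auc$auc, tolerance = 1e-12)
  expect_equal(hi$auc$ci95, lo$auc$ci95, tolerance = 1e-12)
  # reported cutoffs live on the original scale of each direction
  expect_equal(optimal_cutoff(hi$curve)$cutoff,
               -optimal_cutoff(lo$curve)$cutoff, tolerance = 1e-12)
})

test_that("DeLong CI and p agree with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(35)
  for (i in 1:5) {
    inst <- random_roc_instance(40, 25, ties = i > 3)
    mine <- roc_auc(inst$scores, inst$labels, "higher")$auc
    ref <- pROC::roc(response = inst$labels, predictor = inst$scores,
                     levels = c("TRC", "TP"), direction = "<", quiet = TRUE)
    expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
    ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
    expect_equal(mine$ci95, ci[c(1, 3)], tolerance = 1e-8)
    expect_equal(mine$var, as.numeric(pROC::var(ref, method = "delong")),
                 tolerance = 1e-10)
  }
})

test_that("optimal_cutoff maximizes sens*spec with strict calls", {
  r <- roc_auc(c(3, 4, 1, 2), c("TP", "TP", "TRC", "TRC"), "higher")
  co <- optimal_cutoff(r$curve)
  expect_equal(co$cutoff, 2.5)
  expect_equal(co$sens, 1)
  expect_equal(co$spec, 1)
  expect_equal(co$criterion_value, 1)
})

test_that("optimal_cutoff equals exhaustive search on random small instances", {
  set.seed(36)
  for (i in 1:25) {
    inst <- random_roc_instance(sample(3:15, 1), sample(3:15, 1),
                                ties = i %% 3 == 0)
    co <- optimal_cutoff(roc_auc(inst$scores, inst$labels, "higher")$curve)
    u <- sort(unique(inst$scores))
    mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
    brute <- vapply(mids, function(t) {
      calls <- ifelse(inst$scores > t, "TP", "TRC")
      mean(calls[inst$labels == "TP"] == "TP") *
        mean(calls[inst$labels == "TRC"] == "TRC")
    }, numeric(1))
    expect_equal(co$criterion_value, max(brute), tolerance = 1e-12)
  }
})

test_that("product criterion and Youden index can select different cutoffs", {
  # TP: 1 low, 4 middle, 5 high; TRC: 29 low, 21 middle-high.
  scores <- c(0.5, rep(2, 4), rep(4, 5), rep(1, 29), rep(3, 21))
  labels <- rep(c("TP", "TRC"), c(10, 50))
  curve <- roc_auc(scores, labels, "higher")$curve
  co <- optimal_cutoff(curve)
  expect_equal(co$cutoff, 1.5)                       # sens 0.9 * spec 0.58
  expect_equal(co$criterion_value, 0.9 * 0.58)
  fin <- is.finite(curve$thresholds)
  youden <- curve$thresholds[fin][
    which.max(curve$sens[fin] + curve$spec[fin] - 1)]
  expect_equal(youden, 3.5)                          # sens 0.5 at spec 1.0
  expect_false(isTRUE(all.equal(co$cutoff, youden)))
})

test_that("confusion reproduces hand-computed counts and rates", {
  fx <- gen_fig4_fixture()
  stage1 <- ifelse(fx$rCBV_max > 2.85, "TP", "TRC")
  cm <- confusion(stage1, fx$label)
  expect_equal(cm$spec, 1.0)
  expect_equal(cm$ppv, 1.0)
  expect_equal(cm$tp, 44); expect_equal(cm$fn, 39)
  expect_equal(cm$tn, 21); expect_equal(cm$fp, 0)
  expect_equal(cm$acc, 65 / 104)
  expect_equal(round_half_out(cm$acc, 2), 0.63)

  all_right <- confusion(fx$label, fx$label)
  expect_equal(all_right$acc, 1)
  expect_equal(all_right$sens, 1)
  expect_equal(all_right$npv, 1)
  expect_error(confusion(c("TP", "TRC"), "TP"), "equal length")
  nd <- confusion(rep("TP", 4), rep("TP", 4))  # no TRC calls or labels
  expect_true(is.na(nd$spec))
  expect_true(is.na(nd$npv))
})

test_that("Clopper-Pearson intervals reach nominal coverage at cohort sizes", {
  set.seed(11)
  covered <- 0L; total <- 0L
  for (n in c(21, 60, 83, 104)) {
    x <- rbinom(500, n, 0.7)
    for (xx in x) {
      ci <- binom.test(xx, n)$conf.int
      covered <- covered + (ci[1] <= 0.7 && 0.7 <= ci[2])
      total <- total + 1L
    }
  }
  expect_gte(covered / total, 0.95)
})

test_that("cohens_kappa matches hand computation and the e1071 reference", {
  expect_equal(cohens_kappa(c("a", "b", "a"), c("a", "b", "a")), 1)
  # 2x2 agreement table [[20,5],[5,20]]: p_obs 0.8, p_exp 0.5
  a <- rep(c("TP", "TP", "TRC", "TRC"), c(20, 5, 5, 20))
  b <- rep(c("TP", "TRC", "TP", "TRC"), c(20, 5, 5, 20))
  expect_equal(cohens_kappa(a, b), 0.6)
  set.seed(37)
  x <- sample(c("TP", "TRC"), 5000, replace = TRUE)
  y <- sample(c("TP", "TRC"), 5000, replace = TRUE)
  expect_equal(cohens_kappa(x, y), 0, tolerance = 0.05)
  skip_if_not_installed("e1071")
  expect_equal(cohens_kappa(a, b),
               e1071::classAgreement(table(a, b))$kappa, tolerance = 1e-12)
})

test_that("pearson_r behaves on exact lines and rejects degenerate input", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(x, rep(3, 10)), "zero variance")
  expect_error(pearson_r(1:2, 2:3), "at least 3")
})

test_that("cohort_performance assembles the per-parameter report", {
  coh <- separated_cohort(12, 8)
  perf <- cohort_performance(coh)
  expect_equal(nrow(perf), 5)
  row <- perf[perf$parameter == "rCBV_max", ]
  expect_equal(row$auc, 1)
  expect_equal(row$sens, 1)
  expect_equal(row$spec, 1)
  expect_equal(row$median_tp, median(coh$rCBV_max[coh$label == "TP"]))
  slope_row <- perf[perf$parameter == "Slope_suv_per_h", ]
  expect_equal(slope_row$direction, "lower")
  expect_equal(slope_row$auc, 1)   # perfectly separated, lower-positive
})
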