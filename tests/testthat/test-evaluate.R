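# confusion metrics, Wilson intervals, ROC/AUC, baselines, Spearman test

test_that("confusion metrics reproduce the 17-patient worked example", {
  # TP=3 FN=2 TN=11 FP=1: the unique confusion matrix on 17 patients
  calls <- rep(c("HR", "LR", "LR", "HR"), c(3, 2, 11, 1))
  labels <- rep(c(1, 1, 0, 0), c(3, 2, 11, 1))
  cm <- confusion_metrics(calls, labels)
  expect_equal(unname(cm$counts), c(3, 2, 11, 1))
  expect_equal(cm$accuracy, 14 / 17)
  expect_equal(round(cm$accuracy, 2), 0.82)
  expect_equal(cm$sensitivity, 0.60)
  expect_equal(round(cm$specificity, 2), 0.92)

  expect_equal(confusion_metrics(c(1, 1, 0), c(1, 1, 0))$accuracy, 1)
  all_neg <- confusion_metrics(c(0, 0, 0, 0), c(1, 1, 0, 0))
  expect_equal(all_neg$sensitivity, 0)
  expect_equal(all_neg$specificity, 1)
})

test_that("Wilson intervals reproduce every printed two-decimal pair", {
  pairs <- list(
    list(14, 17, c(0.59, 0.94)), list(3, 5, c(0.23, 0.88)),
    list(11, 12, c(0.65, 0.99)), list(10, 17, c(0.36, 0.78)),
    list(12, 17, c(0.47, 0.87)), list(7, 17, c(0.22, 0.64)),
    list(8, 17, c(0.26, 0.69)), list(4, 5, c(0.38, 0.96)),
    list(6, 12, c(0.25, 0.75)), list(9, 12, c(0.47, 0.91)),
    list(4, 12, c(0.14, 0.61)))
  for (p in pairs)
    expect_equal(round(unname(wilson_interval(p[[1]], p[[2]])), 2), p[[3]])

  expect_equal(unname(wilson_interval(9, 9)[2]), 1)   # upper bound at p=1
  expect_equal(unname(wilson_interval(0, 9)[1]), 0)
  expect_error(wilson_interval(3, 0), "n must")
})

test_that("trapezoidal AUC equals U-statistic pair counting, including
          ties", {
  sc <- c(0.9, 0.8, 0.2, 0.1); y <- c(1, 1, 0, 0)
  expect_equal(roc_auc(sc, y)$auc, 1)

  set.seed(61)
  sc2 <- sample(seq(0, 1, by = 0.1), 30, replace = TRUE)  # many ties
  y2 <- rbinom(30, 1, plogis(3 * sc2 - 1.5))
  if (length(unique(y2)) == 1) y2[1] <- 1 - y2[1]
  expect_equal(roc_auc(sc2, y2)$auc, oracle_auc(sc2, y2), tolerance = 1e-12)

  # anti-symmetry
  expect_equal(roc_auc(-sc2, y2)$auc, 1 - roc_auc(sc2, y2)$auc,
               tolerance = 1e-12)

  # independent scores concentrate at 1/2
  set.seed(62)
  sc3 <- rnorm(1000); y3 <- rbinom(1000, 1, 0.4)
  expect_lt(abs(roc_auc(sc3, y3)$auc - 0.5), 0.05)

  const <- roc_auc(rep(1, 10), rep(c(0, 1), 5))
  expect_equal(const$auc, 0.5)
  expect_true(attr(const, "degenerate"))
})

test_that("Spearman test: monotone limit, printed worked example, and
          permutation oracle", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  expect_equal(spearman_test(x, exp(x))$rho, 1)

  # rho = -0.36 at n = 17: two-sided p within 0.01 of the printed 0.15
  p <- spearman_rho_pvalue(-0.36, 17)
  expect_gte(p, 0.15); expect_lte(p, 0.16)
  expect_lt(abs(p - 0.15), 0.01)

  set.seed(63)
  x8 <- rnorm(8); y8 <- 0.6 * x8 + rnorm(8)
  got <- spearman_test(x8, y8)
  orc <- oracle_spearman_perm(x8, y8)
  expect_equal(got$rho, orc$rho, tolerance = 1e-12)
  expect_lt(abs(got$p_value - orc$p), 0.02)

  expect_error(spearman_test(rep(1, 6), rnorm(6)), "rank variance")
})

test_that("clinical baselines use per-variable ROC thresholds with the
          inversion rule", {
  set.seed(70)
  y <- rep(c(0, 1), c(12, 5))
  clin <- data.frame(
    same = y,                           # identical to the label
    anti = -y,                          # perfectly anti-ordered
    vol = rlnorm(17, 8, 1),
    lesions = 1 + rpois(17, 2),
    organs = 1 + rpois(17, 1),
    const = rep(2, 17))
  bl <- clinical_baselines(clin, y)
  expect_equal(nrow(bl), 6)
  expect_equal(bl$accuracy[bl$variable == "same"], 1)
  expect_false(bl$inverted[bl$variable == "same"])
  expect_equal(bl$accuracy[bl$variable == "anti"], 1)  # inversion rescues it
  expect_true(bl$inverted[bl$variable == "anti"])
  expect_equal(bl$flag[bl$variable == "const"], "uninformative")
})

test_that("every reported metric is recomputable from the stored confusion
          counts", {
  set.seed(71)
  sc <- rnorm(20); y <- rbinom(20, 1, 0.4)
  if (length(unique(y)) == 1) y[1] <- 1 - y[1]
  rep_ <- evaluation_report(sc, as.integer(sc > 0), y, n_boot = 200)
  pl <- radsig:::report_payload(rep_)
  expect_equal(pl$accuracy, (pl$counts$TP + pl$counts$TN) /
                 Reduce(`+`, pl$counts))
  expect_true(pl$accuracy >= pl$accuracy_ci[1] &&
                pl$accuracy <= pl$accuracy_ci[2])
  expect_true(pl$auc >= pl$auc_ci[1] && pl$auc <= pl$auc_ci[2])
})
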