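test_that("confusion counts enumerate one-vs-rest cells with symmetry", {
  cc <- confusion_counts(c(0, 0, 1, 1), c(0, 1, 1, 1))
  c1 <- cc[cc$class == 1, ]
  expect_equal(c(c1$TP, c1$FP, c1$FN, c1$TN), c(2L, 1L, 0L, 1L))
  c0 <- cc[cc$class == 0, ]
  expect_equal(c(c0$TP, c0$TN, c0$FP, c0$FN), c(c1$TN, c1$TP, c1$FN, c1$FP))
  expect_true(all(c1$TP + c1$TN + c1$FP + c1$FN == 4))

  perfect <- confusion_counts(c("IDC", "ILC"), c("IDC", "ILC"))
  expect_true(all(perfect$FP == 0) && all(perfect$FN == 0))
  expect_error(confusion_counts(c(0, 1), c(0, 1, 1)), "length mismatch")
})

test_that("metrics recompose accuracy from per-class recalls and supports", {
  for (seed in 1:5) {
    n <- 120
    truth <- withr::with_seed(seed, sample(c("IDC", "ILC"), n, TRUE,
                                           prob = c(0.75, 0.25)))
    pred <- withr::with_seed(seed + 50,
      ifelse(stats::runif(n) < 0.8, truth, sample(c("IDC", "ILC"), n, TRUE)))
    m <- class_metrics(confusion_counts(truth, pred))
    recomposed <- sum(m$recall * m$support) / sum(m$support)
    expect_equal(m$accuracy[1], recomposed, tolerance = 1e-12)
    # row order invariance
    o <- withr::with_seed(seed, sample(n))
    m2 <- class_metrics(confusion_counts(truth[o], pred[o]))
    expect_equal(m, m2)
  }
  # zero denominators yield NA, not errors
  never <- class_metrics(confusion_counts(c("IDC", "IDC", "ILC"),
                                          c("IDC", "IDC", "IDC")))
  expect_true(is.na(never$precision[never$class == 1]))
})

test_that("ROC endpoints behave and match the pROC oracle", {
  truth <- rep(c("IDC", "ILC"), each = 10)
  sep <- c(stats::runif(10, 0, 0.4), stats::runif(10, 0.6, 1))
  expect_equal(roc_auc(sep, truth)$auc, 1)

  null_truth <- rep(c("IDC", "ILC"), 500)
  null_scores <- withr::with_seed(2, stats::runif(1000))
  expect_lt(abs(roc_auc(null_scores, null_truth)$auc - 0.5), 0.06)

  skip_if_not_installed("pROC")
  for (seed in 1:5) {
    withr::with_seed(seed, {
      tr <- sample(c("IDC", "ILC"), 60, TRUE)
      sc <- round(stats::runif(60), 2)   # forces ties
    })
    ours <- roc_auc(sc, tr)$auc
    ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
      response = tr, predictor = sc, levels = c("IDC", "ILC"),
      direction = "<"))))
    expect_equal(ours, ref, tolerance = 1e-12)
    expect_equal(auc_rank(sc, tr), ref, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, rep("IDC", 3)), "both classes")
})

test_that("paired run comparison matches hand arithmetic", {
  b <- c(0.80, 0.82, 0.81)
  a <- b + c(0.05, 0.04, 0.06)
  cmp <- compare_runs(a, b, n_boot = 500, seed = 1)
  expect_equal(cmp$t_statistic, 0.05 / (0.01 / sqrt(3)), tolerance = 1e-9)
  expect_equal(cmp$w_statistic, 0)  # all differences positive
  expect_equal(cmp$mean_difference, 0.05)

  same <- rep(0.9, 10)
  expect_warning(cmp0 <- compare_runs(same, same, n_boot = 100, seed = 1),
                 "zero")
  expect_true(is.na(cmp0$t_statistic))
  expect_true(cmp0$ci_lower <= 0 && cmp0$ci_upper >= 0)

  # t-test and Wilcoxon agree in direction on strongly separated pairs
  a2 <- withr::with_seed(3, stats::runif(40, 0.85, 0.95))
  b2 <- a2 - withr::with_seed(4, stats::runif(40, 0.03, 0.08))
  cmp2 <- compare_runs(a2, b2, n_boot = 2000, seed = 5)
  expect_lt(cmp2$t_p, 0.01)
  expect_lt(cmp2$w_p, 0.01)
  expect_gt(cmp2$ci_lower, 0)
})

test_that("run_experiment returns deterministic per-run rows", {
  tbl <- test_feature_table()
  res <- run_experiment(tbl, "none", n_runs = 5,
                        model = model_spec("RF", list(n_estimators = 100L)),
                        seed = 9)
  expect_equal(nrow(res), 5)
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
  res2 <- run_experiment(tbl, "none", n_runs = 5,
                         model = model_spec("RF", list(n_estimators = 100L)),
                         seed = 9)
  expect_identical(res$accuracy, res2$accuracy)
})
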