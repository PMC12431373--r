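test_that("confusion counts respect the positive-label convention", {
  y <- c(1, 1, 0, 0); p <- c(1, 0, 1, 0)
  cc <- confusion_counts(y, p, positive = 1)
  expect_equal(unname(unclass(cc)), c(1, 1, 1, 1))  # one of each
  expect_equal(sum(cc), 4)

  flipped <- confusion_counts(y, p, positive = 0)
  expect_equal(flipped[["tp"]], cc[["tn"]])
  expect_equal(flipped[["fp"]], cc[["fn"]])

  same <- confusion_counts(c(0, 1, 1), c(0, 1, 1))
  expect_equal(same[["fp"]] + same[["fn"]], 0)
  expect_error(confusion_counts(1, c(1, 0)), "length mismatch")
})

test_that("metric formulas reproduce the reference confusion worked case", {
  m <- classification_metrics(c(tp = 34, tn = 44, fp = 6, fn = 12))
  expect_equal(round(100 * m$accuracy, 2), 81.25)
  expect_equal(round(100 * m$f1, 2), 79.07)
  expect_equal(round(100 * m$precision, 2), 85.00)
  expect_equal(round(100 * m$recall, 2), 73.91)
  expect_false(m$degenerate)
  # f1 never exceeds the larger of precision and recall
  expect_lte(m$f1, max(m$precision, m$recall))

  perfect <- classification_metrics(c(tp = 10, tn = 0, fp = 0, fn = 0))
  expect_equal(c(perfect$accuracy, perfect$precision, perfect$recall,
                 perfect$f1), rep(1, 4))

  expect_warning(dg <- classification_metrics(c(tp = 0, tn = 3, fp = 0, fn = 2)),
                 "precision undefined")
  expect_equal(dg$precision, 0)
  expect_equal(dg$recall, 0)
  expect_true(dg$degenerate)
  expect_error(classification_metrics(c(tp = 0, tn = 0, fp = 0, fn = 0)),
               "no samples")
})

test_that("rank-statistic AUC equals brute-force pair counting", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)

  # 6-point hand case: count concordant pairs / (3 * 3)
  y <- c(1, 1, 0, 0, 1, 0); s <- c(0.9, 0.6, 0.7, 0.2, 0.8, 0.4)
  brute <- mean(outer(s[y == 1], s[y == 0], ">") +
                  0.5 * outer(s[y == 1], s[y == 0], "=="))
  expect_equal(roc_auc(y, s), brute)
  expect_equal(brute, 8 / 9)

  # ties handled by midrank, cross-checked against pROC on random data
  set.seed(17)
  yy <- rbinom(50, 1, 0.5); ss <- round(runif(50), 1)
  brute2 <- mean(outer(ss[yy == 1], ss[yy == 0], ">") +
                   0.5 * outer(ss[yy == 1], ss[yy == 0], "=="))
  expect_equal(roc_auc(yy, ss), brute2)
  expect_equal(roc_auc(yy, ss),
               as.numeric(suppressMessages(
                 pROC::roc(yy, ss, levels = c("0", "1"),
                           direction = "<")$auc)))
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "single class")
})

test_that("per-sample timing reproduces the reference division", {
  t <- per_sample_times(224, 95, 224, 95)
  expect_equal(t$per_sample_train_ms, 1)
  expect_equal(t$per_sample_test_ms, 1)
  expect_equal(round(per_sample_times(230.46, 1, 224, 95)$per_sample_train_ms,
                     2), 1.03)
  expect_error(per_sample_times(1, 1, 0, 95), "positive")
})

test_that("Cramer's V detects perfect association and rejects noise", {
  a <- rep(c(0, 1), each = 50)
  expect_equal(cramers_v(a, a), 1)
  expect_equal(cramers_v(a, 1 - a), 1)    # relabeling invariance
  tab22 <- c(rep(0, 50), rep(1, 50))
  expect_equal(cramers_v(tab22, tab22), 1)

  set.seed(23)
  x <- rbinom(1e4, 1, 0.5); y <- rbinom(1e4, 1, 0.5)
  expect_lt(cramers_v(x, y), 0.05)

  # symmetry, including a continuous variable through quantile binning
  set.seed(24)
  cont <- rnorm(200); lab <- rbinom(200, 1, 0.5)
  expect_equal(cramers_v(cont, lab), cramers_v(lab, cont))
  expect_warning(v0 <- cramers_v(rep(1, 30), rbinom(30, 1, 0.5)), "constant")
  expect_equal(v0, 0)

  # the screen ranks a strongly associated feature first
  sim <- simulate_gallstone(synthetic_spec(seed = 12))
  scr <- association_screen(sim$dataset)
  expect_true(scr$name[1] %in% c("CRP", "Vitamin D", "AAST"))
})

test_that("misclassification profiles equal a spreadsheet-style oracle", {
  cases <- cases_to_dataset(extdata("misclassified_cases_example.csv"))
  fn_prof <- misclassification_profile(cases$ds, cases$y_pred,
                                       "false_negative",
                                       features = c(35L, 30L, 37L))
  expect_equal(fn_prof$mean[fn_prof$feature == "CRP"], 0.718)
  expect_equal(fn_prof$mean[fn_prof$feature == "AAST"], 15.4)
  expect_equal(fn_prof$mean[fn_prof$feature == "Vitamin D"], 16.626)

  fp_prof <- misclassification_profile(cases$ds, cases$y_pred,
                                       "false_positive",
                                       features = c(35L, 30L, 37L))
  expect_equal(round(fp_prof$mean[fp_prof$feature == "CRP"], 3), 0.279)
  expect_equal(fp_prof$mean[fp_prof$feature == "AAST"], 188 / 9)

  # independent mean computation over the raw long table
  raw <- read.csv(extdata("misclassified_cases_example.csv"))
  oracle <- with(subset(raw, group == "false_negative" & feature == "ALP"),
                 mean(value))
  fn_all <- misclassification_profile(cases$ds, cases$y_pred, "false_negative")
  expect_equal(fn_all$mean[fn_all$feature == "ALP"], oracle)

  # single-row group: mean equals the row; empty group: empty table
  single <- misclassification_profile(cases$ds,
                                      ifelse(seq_len(14) == 1, 1L, cases$ds$y),
                                      "false_negative", features = 35L)
  expect_equal(single$mean, cases$ds$X[1, "CRP"][[1]])
  none <- misclassification_profile(cases$ds, cases$ds$y, "false_negative")
  expect_true(all(is.na(none$mean)))
})

test_that("the max-depth sweep exposes overfitting on noisy data", {
  sim <- simulate_gallstone(synthetic_spec(seed = 1))
  sp <- make_splits(sim$dataset, 3, 0.7, seed = 1)
  base <- gs_candidate(0:37, c(150, 10, 2, 1))
  tabs <- lapply(1:3, function(f) {
    tr <- sp[[f]]$train; te <- sp[[f]]$test
    depth_sweep(sim$dataset$X[tr, ], sim$dataset$y[tr],
                sim$dataset$X[te, ], sim$dataset$y[te],
                depths = c(1, 2, 12, 16), base, seed = 7)
  })
  expect_equal(tabs[[1]]$depth, c(1, 2, 12, 16))
  gap <- rowMeans(sapply(tabs, `[[`, "gap_pct"))
  train_acc <- rowMeans(sapply(tabs, `[[`, "train_accuracy"))
  # shallow stumps barely overfit; deep trees memorize the training slice
  expect_lt(gap[1], 5)
  expect_gt(train_acc[4], 0.95)
  expect_gt(gap[4], gap[1])

  tr <- sp[[1]]$train; te <- sp[[1]]$test
  tab2 <- depth_sweep(sim$dataset$X[tr, ], sim$dataset$y[tr],
                      sim$dataset$X[te, ], sim$dataset$y[te],
                      depths = c(1, 2, 12, 16), base, seed = 7)
  expect_identical(tabs[[1]], tab2)
  expect_error(depth_sweep(sim$dataset$X, sim$dataset$y, sim$dataset$X,
                           sim$dataset$y, integer(0), base), "non-empty")
})
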