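small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_gallstone(synthetic_spec(seed = 19))
      cache <<- list(sim = sim,
                     fit = scso_rf(sim$dataset, n_splits = 3,
                                   control = scso_control(8, 4), seed = 19))
    }
    cache
  }
})

test_that("scso_rf returns a coherent fitted-model object", {
  fx <- small_fit()
  fit <- fx$fit
  expect_s3_class(fit, "scso_rf")
  expect_length(fit$folds, 3)
  for (f in fit$folds) expect_true(all(f$candidate$features %in% fit$config$features))
  expect_true(all(fit$config$phi >= c(100, 3, 2, 1)))

  # methods
  expect_output(print(fit), "Consolidated features")
  expect_output(print(summary(fit)), "Per-fold optimization outcomes")
  co <- coef(fit)
  expect_named(co, c("n_trees", "max_depth", "min_split", "min_leaf",
                     "features"))
  pr <- predict(fit, fx$sim$dataset, type = "prob")
  expect_length(pr, 319)
  expect_true(all(pr >= 0 & pr <= 1))
  cl <- predict(fit, fx$sim$dataset$X[1:5, ])
  expect_true(all(cl %in% c(0L, 1L)))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("the mean metrics row is the arithmetic mean of the fold rows", {
  fm <- small_fit()$fit$fold_metrics
  folds <- fm[fm$fold != "mean", ]
  means <- fm[fm$fold == "mean", ]
  for (col in c("accuracy", "f1", "precision", "recall", "auc")) {
    expect_equal(means[[col]], mean(folds[[col]]), tolerance = 1e-12)
  }
})

test_that("simulate stage writes reproducible artifacts", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  gs_simulate(d1, synthetic_spec(seed = 44))
  gs_simulate(d2, synthetic_spec(seed = 44))
  expect_identical(readLines(file.path(d1, "data.csv")),
                   readLines(file.path(d2, "data.csv")))
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(unlist(man$signal_indices), c(35, 37, 30))
  expect_error(gs_simulate(withr::local_tempdir(),
                           synthetic_spec(n_samples = 0L,
                                          class_counts = c(0L, 0L))))
})

test_that("optimize stage emits one outcome per fold plus the consolidation", {
  sim <- simulate_gallstone(synthetic_spec(n_samples = 120,
                                           class_counts = c(60L, 60L),
                                           seed = 9))
  out <- withr::local_tempdir()
  res <- gs_optimize(sim$dataset, out, n_splits = 3,
                     control = scso_control(6, 3), seed = 9)
  expect_length(list.files(out, pattern = "^fold_"), 3)
  expect_length(list.files(out, pattern = "^history_"), 3)
  expect_true(file.exists(file.path(out, "final_config.json")))
  expect_true(file.exists(file.path(out, "splits.json")))
  for (f in res$folds) expect_false(is.unsorted(f$history))
  fc <- jsonlite::read_json(file.path(out, "final_config.json"))
  expect_equal(unlist(fc$features), res$config$features)
})

test_that("evaluation stage runs all four frameworks and intersects errors", {
  fx <- small_fit()
  ds <- fx$sim$dataset
  ev <- gs_evaluate(ds, fx$fit$splits, fx$fit$config,
                    out_dir = withr::local_tempdir(), seed = 19)
  expect_named(ev$metrics, c("baseline_single", "baseline_cv",
                             "optimized_single", "optimized_cv"))
  expect_equal(nrow(ev$metrics$baseline_single), 2)  # one fold + mean
  expect_equal(nrow(ev$metrics$optimized_cv), 4)
  for (m in ev$metrics) {
    expect_true(all(m$accuracy >= 0 & m$accuracy <= 1))
  }
  # the always-misclassified set is contained in each framework's set
  for (s in ev$misclassified) {
    expect_true(all(ev$always_misclassified %in% s))
  }
})

test_that("explanation stage: additivity holds and actionability is enforced", {
  fx <- small_fit()
  ds <- fx$sim$dataset
  fit <- fx$fit
  # keep the enumeration small: restrict to a compact consolidated set
  if (length(fit$config$features) > 8) {
    fit$config <- gs_candidate(fit$config$features[1:8], fit$config$phi)
    fit$model <- fit_forest(ds$X, ds$y, fit$config, seed = 19)
  }
  out <- withr::local_tempdir()
  res <- gs_explain(fit, ds, indices = c(2, 7), out_dir = out,
                    background_size = 30, counterfactuals = TRUE,
                    k = 2, cf_control = scso_control(10, 8), seed = 19)
  for (ex in res$explanations) {
    expect_lt(abs(ex$base_value + sum(ex$phi) - ex$prediction), 1e-9)
  }
  expect_equal(sort(res$ranking$index), sort(fit$config$features))
  for (cf in res$cfs) {
    untouched <- setdiff(0:37, cf$query$actionable) + 1
    for (j in untouched) {
      expect_true(all(cf$candidates[, j] == cf$query$instance[j]))
    }
    expect_true(all(cf$predicted_class[cf$valid] == cf$query$target_class))
  }
  expect_length(list.files(out, pattern = "^shap_row"), 2)
  expect_error(gs_explain(fit, ds, indices = 999), "out of range")
})
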