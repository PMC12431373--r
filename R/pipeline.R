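#' Write a synthetic dataset and its manifest
#'
#' Stage runner: generates a synthetic gallstone-schema dataset and writes
#' `data.csv` plus `manifest.json` (the planted-signal ground truth) to the
#' output directory. Same spec, same files, byte for byte.
#'
#' @param out_dir output directory (created if needed).
#' @param spec a [synthetic_spec()].
#' @return Invisibly, the list of written paths.
#' @export
gs_simulate <- function(out_dir, spec = synthetic_spec()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_gallstone(spec)
  data_path <- file.path(out_dir, "data.csv")
  manifest_path <- file.path(out_dir, "manifest.json")
  write_gallstone_csv(sim$dataset, data_path)
  jsonlite::write_json(sim$manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(data = data_path, manifest = manifest_path))
}

#' Run the per-fold optimization stage and write its artifacts
#'
#' Builds the split plan, runs the sand cat search on every training slice
#' (test rows of a fold are never touched during that fold's optimization),
#' consolidates, and writes per-fold outcome JSONs, convergence-history
#' CSVs, the split manifest and the final configuration.
#'
#' @param ds a [gs_dataset()] or path to a CSV readable by
#'   [load_gallstone_csv()].
#' @param out_dir output directory.
#' @param n_splits,train_fraction split plan parameters.
#' @param control an [scso_control()].
#' @param fitness_mode see [candidate_fitness()].
#' @param seed master seed.
#' @return Invisibly, a list with `folds`, `config` and the written paths.
#' @export
gs_optimize <- function(ds, out_dir, n_splits = 10L, train_fraction = 0.7,
                        control = scso_control(), fitness_mode = "train_f1",
                        seed = 1L) {
  if (is.character(ds)) ds <- load_gallstone_csv(ds, quiet = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  splits <- make_splits(ds, n_splits = n_splits,
                        train_fraction = train_fraction, seed = seed)
  write_split_manifest(splits, file.path(out_dir, "splits.json"))
  space <- search_space(ncol(ds$X))
  ctrl <- control
  ctrl$seed <- NULL
  set.seed(seed)
  folds <- vector("list", length(splits))
  for (f in seq_along(splits)) {
    tr <- splits[[f]]$train
    folds[[f]] <- optimize_fold(ds$X[tr, , drop = FALSE], ds$y[tr], space,
                                ctrl, mode = fitness_mode,
                                model_seed = seed + f)
    write_candidate_json(folds[[f]],
                         file.path(out_dir, sprintf("fold_%02d.json", f)))
    write_history_csv(folds[[f]],
                      file.path(out_dir, sprintf("history_%02d.csv", f)))
  }
  config <- consolidate_folds(folds)
  write_candidate_json(config, file.path(out_dir, "final_config.json"))
  invisible(list(folds = folds, config = config, splits = splits,
                 out_dir = out_dir))
}

#' Evaluate baseline and consolidated configurations, with artifacts
#'
#' Runs the four evaluation frameworks of the reference protocol: the
#' baseline (all features, default-style hyperparameters) on a single
#' split and over all splits, and the consolidated configuration on the
#' same single split and over all splits. Writes per-fold metric tables and
#' reports the rows misclassified in every framework.
#'
#' @param ds a [gs_dataset()].
#' @param splits a `gs_splits`.
#' @param config consolidated [gs_candidate()].
#' @param out_dir output directory (`NULL` to skip writing).
#' @param baseline baseline [gs_candidate()]; default all features with
#'   forest defaults (300 trees, depth 10, split 2, leaf 1).
#' @param seed base forest seed.
#' @param positive positive label for the metrics.
#' @return A list with `metrics` (named list of the four framework
#'   tables), `misclassified` (per-framework row indices) and
#'   `always_misclassified` (their intersection).
#' @export
gs_evaluate <- function(ds, splits, config, out_dir = NULL,
                        baseline = NULL, seed = 1L, positive = 1L) {
  if (is.null(baseline)) {
    baseline <- gs_candidate(ds$schema$index, c(300L, 10L, 2L, 1L))
  }
  single <- structure(splits[1], class = "gs_splits",
                      n = attr(splits, "n"), seed = attr(splits, "seed"),
                      train_fraction = attr(splits, "train_fraction"))
  frameworks <- list(
    baseline_single = list(cand = baseline, sp = single),
    baseline_cv = list(cand = baseline, sp = splits),
    optimized_single = list(cand = config, sp = single),
    optimized_cv = list(cand = config, sp = splits)
  )
  metrics <- lapply(frameworks, function(fw) {
    evaluate_config(ds, fw$sp, fw$cand, seed = seed, positive = positive)
  })
  misclassified <- lapply(frameworks, function(fw) {
    bad <- integer(0)
    for (f in seq_along(fw$sp)) {
      tr <- fw$sp[[f]]$train; te <- fw$sp[[f]]$test
      fit <- fit_forest(ds$X[tr, , drop = FALSE], ds$y[tr], fw$cand,
                        seed = seed + f)
      pred <- predict(fit, ds$X[te, , drop = FALSE])
      bad <- union(bad, te[pred != ds$y[te]])
    }
    sort(bad)
  })
  always <- Reduce(intersect, misclassified)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(metrics)) {
      utils::write.csv(metrics[[nm]],
                       file.path(out_dir, paste0("metrics_", nm, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(list(misclassified = misclassified,
                              always_misclassified = always),
                         file.path(out_dir, "misclassified.json"))
  }
  list(metrics = metrics, misclassified = misclassified,
       always_misclassified = always)
}

#' Explain individual predictions, with artifacts
#'
#' For each requested row: an exact Shapley explanation of the fitted
#' model over its consolidated feature set against a seeded background
#' subsample of the data, and (optionally) a diverse counterfactual set
#' over the actionable features. Writes explanation JSONs, the mean-|phi|
#' ranking and counterfactual tables.
#'
#' @param fit an [scso_rf()] fit.
#' @param ds the [gs_dataset()] it was fitted on.
#' @param indices 1-based row numbers to explain.
#' @param out_dir output directory (`NULL` to skip writing).
#' @param background_size background subsample cap (default 100).
#' @param counterfactuals if TRUE also run the counterfactual search.
#' @param actionable 0-based actionable feature indices for the
#'   counterfactual search (default CRP, Vitamin D, AAST).
#' @param k counterfactuals per instance.
#' @param cf_control an [scso_control()] for the counterfactual search.
#' @param seed seed for the background subsample and searches.
#' @return A list with `explanations`, `ranking` and (optionally) `cfs`.
#' @export
gs_explain <- function(fit, ds, indices, out_dir = NULL,
                       background_size = 100L, counterfactuals = FALSE,
                       actionable = c(35L, 37L, 30L), k = 4L,
                       cf_control = scso_control(pop_size = 30L,
                                                 max_iter = 40L),
                       seed = 1L) {
  stopifnot(inherits(fit, "scso_rf"))
  if (any(indices < 1L | indices > nrow(ds$X))) stop("index out of range")
  set.seed(seed)
  bg_rows <- sample(nrow(ds$X), min(background_size, nrow(ds$X)))
  background <- ds$X[bg_rows, , drop = FALSE]
  explanations <- lapply(indices, function(i) {
    exact_shapley(fit$model, ds$X[i, ], background, fit$config$features)
  })
  names(explanations) <- paste0("row_", indices)
  ranking <- mean_abs_shapley(explanations)
  ranking$name <- ds$schema$name[match(ranking$index, ds$schema$index)]
  cfs <- NULL
  if (counterfactuals) {
    ranges <- apply(ds$X[, actionable + 1L, drop = FALSE], 2, range)
    cfs <- lapply(seq_along(indices), function(ii) {
      i <- indices[ii]
      current <- as.integer(predict_prob(fit$model, ds$X[i, , drop = FALSE]) > 0.5)
      q <- cf_query(ds$X[i, ], target_class = 1L - current, k = k,
                    actionable = actionable, ranges = ranges)
      ctl <- cf_control
      ctl$seed <- seed + ii
      generate_counterfactuals(fit$model, q, ds$X, ctl)
    })
    names(cfs) <- paste0("row_", indices)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(explanations)) {
      write_shapley_json(explanations[[nm]],
                         file.path(out_dir, paste0("shap_", nm, ".json")))
    }
    utils::write.csv(ranking, file.path(out_dir, "shap_ranking.csv"),
                     row.names = FALSE)
    if (counterfactuals) {
      for (nm in names(cfs)) {
        utils::write.csv(cf_table(cfs[[nm]], ds$schema),
                         file.path(out_dir, paste0("cf_", nm, ".csv")),
                         row.names = FALSE)
      }
    }
  }
  list(explanations = explanations, ranking = ranking, cfs = cfs)
}
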