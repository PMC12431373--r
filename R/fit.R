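#' Fit an SCSO-optimized random forest
#'
#' The package's central estimator. The data are split into `n_splits`
#' repeated stratified 70/30 train/test folds; each fold's training slice
#' is searched independently by the sand cat swarm for a joint feature
#' subset and forest hyperparameter set (fitness = F1 of the delegated
#' Gini forest); the fold winners are consolidated by feature union and
#' per-parameter mode; the consolidated configuration is evaluated on every
#' fold's held-out slice and finally refitted on the full data for
#' prediction.
#'
#' @param x numeric feature matrix/data.frame, a [gs_dataset()], or a
#'   formula.
#' @param y 0/1 labels (ignored when `x` is a `gs_dataset` or formula).
#' @param data data.frame holding the formula variables.
#' @param n_splits number of repeated splits (default 10).
#' @param train_fraction training fraction per split (default 0.7).
#' @param control an [scso_control()] for the per-fold search; the
#'   reference configuration is 50 agents and 100 iterations.
#' @param fitness_mode `"train_f1"` (reference behaviour) or
#'   `"holdout_f1"`.
#' @param positive positive label for the evaluation metrics (default 1).
#' @param seed master seed: drives the split plan, the per-fold searches
#'   and every forest fit.
#' @param ... passed between methods.
#' @return An object of class `scso_rf`: list with `config` (the
#'   consolidated [gs_candidate()]), `folds` (per-fold `gs_fold` outcomes),
#'   `fold_metrics` (per-fold test metrics of the consolidated
#'   configuration, plus a mean row), `model` (final `gs_forest` fitted on
#'   all rows), `splits`, `schema`, `call`.
#' @examples
#' \donttest{
#' sim <- simulate_gallstone(synthetic_spec(seed = 7))
#' fit <- scso_rf(sim$dataset, n_splits = 2,
#'                control = scso_control(pop_size = 10, max_iter = 5),
#'                seed = 7)
#' print(fit)
#' summary(fit)
#' }
#' @export
scso_rf <- function(x, ...) UseMethod("scso_rf")

#' @rdname scso_rf
#' @export
scso_rf.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  X <- mf[, -1, drop = FALSE]
  sch <- data.frame(index = seq_len(ncol(X)) - 1L, name = names(X),
                    kind = "continuous", description = names(X))
  out <- scso_rf.default(gs_dataset(X, y, sch), ...)
  out$call <- match.call()
  out
}

#' @rdname scso_rf
#' @export
scso_rf.gs_dataset <- function(x, ...) {
  out <- scso_rf_impl(x, ...)
  out$call <- match.call()
  out
}

#' @rdname scso_rf
#' @export
scso_rf.default <- function(x, y, ...) {
  X <- as.matrix(x)
  sch <- data.frame(index = seq_len(ncol(X)) - 1L,
                    name = if (is.null(colnames(X)))
                      paste0("x", seq_len(ncol(X)) - 1L) else colnames(X),
                    kind = "continuous", description = "")
  out <- scso_rf_impl(gs_dataset(X, y, sch), ...)
  out$call <- match.call()
  out
}

scso_rf_impl <- function(ds, n_splits = 10L, train_fraction = 0.7,
                         control = scso_control(), fitness_mode = "train_f1",
                         positive = 1L, seed = 1L) {
  splits <- make_splits(ds, n_splits = n_splits,
                        train_fraction = train_fraction, seed = seed)
  space <- search_space(ncol(ds$X))
  ctrl <- control
  ctrl$seed <- NULL
  set.seed(seed)
  folds <- lapply(seq_along(splits), function(f) {
    tr <- splits[[f]]$train
    optimize_fold(ds$X[tr, , drop = FALSE], ds$y[tr], space, ctrl,
                  mode = fitness_mode, model_seed = seed + f)
  })
  config <- consolidate_folds(folds)
  fold_metrics <- evaluate_config(ds, splits, config, seed = seed,
                                  positive = positive)
  model <- fit_forest(ds$X, ds$y, config, seed = seed)
  structure(list(config = config, folds = folds,
                 fold_metrics = fold_metrics, model = model,
                 splits = splits, schema = ds$schema,
                 positive = positive, seed = seed, call = sys.call(-1)),
            class = "scso_rf")
}

#' Evaluate a configuration over a split plan
#'
#' Fits the candidate on each split's training slice, scores the held-out
#' slice, and appends an arithmetic mean row.
#'
#' @param ds a [gs_dataset()].
#' @param splits a `gs_splits`.
#' @param candidate a [gs_candidate()].
#' @param seed base forest seed (fold `f` uses `seed + f`).
#' @param positive positive label for the metrics.
#' @return data.frame with per-fold rows and a final `"mean"` row:
#'   accuracy, F1, precision, recall, AUC (fractions) and train/test wall
#'   times in ms.
#' @export
evaluate_config <- function(ds, splits, candidate, seed = 1L, positive = 1L) {
  rows <- lapply(seq_along(splits), function(f) {
    tr <- splits[[f]]$train; te <- splits[[f]]$test
    t0 <- proc.time()[["elapsed"]]
    fit <- fit_forest(ds$X[tr, , drop = FALSE], ds$y[tr], candidate,
                      seed = seed + f)
    t1 <- proc.time()[["elapsed"]]
    prob <- predict(fit, ds$X[te, , drop = FALSE], type = "prob")
    t2 <- proc.time()[["elapsed"]]
    pred <- as.integer(prob > 0.5)
    m <- classification_metrics(confusion_counts(ds$y[te], pred, positive))
    data.frame(fold = f, accuracy = m$accuracy, f1 = m$f1,
               precision = m$precision, recall = m$recall,
               auc = roc_auc(ds$y[te], prob, positive),
               train_ms = 1000 * (t1 - t0), test_ms = 1000 * (t2 - t1))
  })
  out <- do.call(rbind, rows)
  mean_row <- out[1, ]
  mean_row$fold <- NA
  mean_row[-1] <- colMeans(out[-1])
  out <- rbind(out, mean_row)
  out$fold <- c(seq_along(splits), "mean")
  rownames(out) <- NULL
  out
}

#' @export
print.scso_rf <- function(x, ...) {
  cat("SCSO-optimized random forest\n\n")
  cat("Call:\n  "); print(x$call)
  nm <- x$schema$name[match(x$config$features, x$schema$index)]
  cat(sprintf("\nConsolidated features (%d of %d): %s\n",
              length(x$config$features), nrow(x$schema),
              paste(sprintf("%d:%s", x$config$features, nm), collapse = ", ")))
  cat(sprintf("Consolidated hyperparameters: trees=%d depth=%d split=%d leaf=%d\n",
              x$config$phi[1], x$config$phi[2], x$config$phi[3],
              x$config$phi[4]))
  mm <- x$fold_metrics[x$fold_metrics$fold == "mean", ]
  cat(sprintf("Mean held-out: accuracy %.2f%%, F1 %.2f%%, AUC %.3f over %d splits\n",
              100 * mm$accuracy, 100 * mm$f1, mm$auc,
              length(x$splits)))
  invisible(x)
}

#' @export
summary.scso_rf <- function(object, ...) {
  structure(list(fold_metrics = object$fold_metrics,
                 config = object$config,
                 folds = lapply(object$folds, function(f)
                   list(features = f$candidate$features,
                        phi = f$candidate$phi, fitness = f$fitness)),
                 schema = object$schema),
            class = "summary.scso_rf")
}

#' @export
print.summary.scso_rf <- function(x, ...) {
  cat("Per-fold optimization outcomes:\n")
  for (i in seq_along(x$folds)) {
    f <- x$folds[[i]]
    cat(sprintf("  fold %2d: fitness %.3f, features {%s}, phi (%d,%d,%d,%d)\n",
                i, f$fitness, paste(f$features, collapse = ","),
                f$phi[1], f$phi[2], f$phi[3], f$phi[4]))
  }
  cat("\nHeld-out metrics of the consolidated configuration:\n")
  fm <- x$fold_metrics
  fm[, c("accuracy", "f1", "precision", "recall")] <-
    round(100 * fm[, c("accuracy", "f1", "precision", "recall")], 2)
  fm$auc <- round(fm$auc, 3)
  fm$train_ms <- round(fm$train_ms, 1); fm$test_ms <- round(fm$test_ms, 2)
  print(fm, row.names = FALSE)
  invisible(x)
}

#' @export
predict.scso_rf <- function(object, newdata, type = c("class", "prob"), ...) {
  if (inherits(newdata, "gs_dataset")) newdata <- newdata$X
  predict(object$model, newdata, type = match.arg(type))
}

#' @export
coef.scso_rf <- function(object, ...) {
  c(as.list(object$config$phi),
    list(features = object$config$features))
}

#' Convergence plot of the per-fold swarm searches
#'
#' Plots each fold's best-fitness history against the iteration number.
#'
#' @param x an `scso_rf` fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.scso_rf <- function(x, ...) {
  H <- do.call(cbind, lapply(x$folds, `[[`, "history"))
  graphics::matplot(H, type = "l", lty = 1, xlab = "iteration",
                    ylab = "best fitness (F1)",
                    main = "Per-fold SCSO convergence", ...)
  invisible(x)
}
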