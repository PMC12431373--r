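#' Confusion counts with an explicit positive label
#'
#' @param y_true,y_pred equal-length 0/1 label vectors.
#' @param positive which label is scored as the positive class. The package
#'   default is 1 ("absence"); clinical profiling functions use 0 ("disease
#'   present") instead, see [misclassification_profile()].
#' @return Named integer vector of class `gs_confusion`: `tp`, `tn`, `fp`,
#'   `fn`. Counts sum to the number of samples; flipping `positive` swaps
#'   tp with tn and fp with fn.
#' @export
confusion_counts <- function(y_true, y_pred, positive = 1L) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) stop("labels must be 0/1")
  pos_t <- y_true == positive; pos_p <- y_pred == positive
  structure(c(tp = sum(pos_t & pos_p), tn = sum(!pos_t & !pos_p),
              fp = sum(!pos_t & pos_p), fn = sum(pos_t & !pos_p)),
            class = "gs_confusion")
}

#' Classification metrics from confusion counts
#'
#' Computes accuracy `(tp + tn) / n`, precision `tp / (tp + fp)`, recall
#' `tp / (tp + fn)` and F1 (harmonic mean of precision and recall). An
#' undefined 0/0 ratio is reported as 0 and flagged with a warning, so
#' batch reports never fail on degenerate folds.
#'
#' @param counts a `gs_confusion` from [confusion_counts()], or a named
#'   vector/list with `tp`, `tn`, `fp`, `fn`.
#' @return A list of class `gs_metrics` with `accuracy`, `precision`,
#'   `recall`, `f1` (all fractions in `[0, 1]`), the `counts`, and
#'   `degenerate` (TRUE if any ratio was 0/0).
#' @examples
#' m <- classification_metrics(c(tp = 34, tn = 44, fp = 6, fn = 12))
#' round(100 * c(m$accuracy, m$f1, m$precision, m$recall), 2)
#' @export
classification_metrics <- function(counts) {
  cc <- c(tp = as.numeric(counts[["tp"]]), tn = as.numeric(counts[["tn"]]),
          fp = as.numeric(counts[["fp"]]), fn = as.numeric(counts[["fn"]]))
  n <- sum(cc)
  if (n == 0) stop("no samples")
  degenerate <- FALSE
  ratio <- function(num, den, what) {
    if (den == 0) {
      degenerate <<- TRUE
      warning(sprintf("%s undefined (0/0); reported as 0", what), call. = FALSE)
      return(0)
    }
    num / den
  }
  accuracy <- (cc[["tp"]] + cc[["tn"]]) / n
  precision <- ratio(cc[["tp"]], cc[["tp"]] + cc[["fp"]], "precision")
  recall <- ratio(cc[["tp"]], cc[["tp"]] + cc[["fn"]], "recall")
  f1 <- if (precision + recall == 0) {
    degenerate <- TRUE
    0
  } else 2 * precision * recall / (precision + recall)
  structure(list(accuracy = accuracy, precision = precision, recall = recall,
                 f1 = f1, counts = cc, degenerate = degenerate),
            class = "gs_metrics")
}

#' @export
print.gs_metrics <- function(x, digits = 2, ...) {
  cat(sprintf("accuracy %.*f%%  f1 %.*f%%  precision %.*f%%  recall %.*f%%\n",
              digits, 100 * x$accuracy, digits, 100 * x$f1,
              digits, 100 * x$precision, digits, 100 * x$recall))
  invisible(x)
}

#' Area under the ROC curve by the rank statistic
#'
#' Computes AUC as the Wilcoxon rank statistic (the probability that a
#' random positive scores above a random negative), with midranks for tied
#' scores; equivalent to the trapezoid rule over all thresholds.
#'
#' @param y_true 0/1 labels containing both classes.
#' @param scores numeric scores in `[0, 1]` (probability of the positive
#'   class).
#' @param positive positive label (default 1).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(y_true, scores, positive = 1L) {
  if (length(y_true) != length(scores)) stop("length mismatch")
  pos <- as.integer(y_true) == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: y_true has a single class")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' False/true positive rates at every threshold, for CSV export and
#' plotting.
#'
#' @inheritParams roc_auc
#' @return data.frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(y_true, scores, positive = 1L) {
  pos <- as.integer(y_true) == positive
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  data.frame(
    threshold = th,
    fpr = vapply(th, function(t) mean(scores[!pos] >= t), numeric(1)),
    tpr = vapply(th, function(t) mean(scores[pos] >= t), numeric(1))
  )
}

#' Per-sample training and testing time
#'
#' Divides measured per-fold wall times by the corresponding sample counts,
#' the convention used to report the reference protocol's 224-train /
#' 95-test folds in milliseconds per sample.
#'
#' @param total_train_ms,total_test_ms total durations in milliseconds.
#' @param n_train,n_test positive sample counts.
#' @return A list of class `gs_timing` with the totals and
#'   `per_sample_train_ms`, `per_sample_test_ms`.
#' @examples
#' per_sample_times(230.46, 15.03, 224, 96)$per_sample_train_ms # ~1.03
#' @export
per_sample_times <- function(total_train_ms, total_test_ms, n_train, n_test) {
  if (n_train <= 0 || n_test <= 0) stop("sample counts must be positive")
  structure(list(total_train_ms = total_train_ms,
                 total_test_ms = total_test_ms,
                 per_sample_train_ms = total_train_ms / n_train,
                 per_sample_test_ms = total_test_ms / n_test),
            class = "gs_timing")
}

#' Cramér's V association between two variables
#'
#' Chi-square based association on the contingency table of the two
#' (discretized) variables, normalized to `[0, 1]`:
#' `V = sqrt(chi2 / (n * (min(r, c) - 1)))`, classic formula without bias
#' correction. Continuous inputs (more distinct values than `bins`) are
#' discretized into quantile bins first.
#'
#' @param a,b equal-length vectors.
#' @param bins number of quantile bins for continuous inputs (default 4,
#'   i.e. quartiles).
#' @return V in `[0, 1]`. A constant vector yields 0 with a warning.
#' @export
cramers_v <- function(a, b, bins = 4L) {
  if (length(a) != length(b)) stop("length mismatch")
  if (bins < 2L) stop("bins must be >= 2")
  da <- discretize_quantile(a, bins)
  db <- discretize_quantile(b, bins)
  if (length(unique(da)) < 2L || length(unique(db)) < 2L) {
    warning("constant vector: V reported as 0", call. = FALSE)
    return(0)
  }
  tab <- table(da, db)
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
  v <- sqrt(as.numeric(chi2) / (sum(tab) * (min(dim(tab)) - 1)))
  min(v, 1)
}

discretize_quantile <- function(x, bins) {
  ux <- unique(x)
  if (length(ux) <= bins) return(as.character(x))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1)))
  if (length(br) < 3L) return(as.character(x >= br[length(br)]))
  as.character(cut(x, breaks = br, include.lowest = TRUE))
}

#' Association screen of every feature against the target
#'
#' Cramér's V of each schema feature against the class label, the package's
#' univariate association diagnostic.
#'
#' @param ds a [gs_dataset()].
#' @param bins quantile bins for continuous features.
#' @return data.frame with `index`, `name`, `cramers_v`, sorted descending.
#' @export
association_screen <- function(ds, bins = 4L) {
  stopifnot(inherits(ds, "gs_dataset"))
  v <- vapply(seq_len(ncol(ds$X)),
              function(j) cramers_v(ds$X[, j], ds$y, bins), numeric(1))
  out <- data.frame(index = ds$schema$index, name = ds$schema$name,
                    cramers_v = v)
  out[order(-out$cramers_v), ]
}

#' Clinical profile of misclassified cases
#'
#' Selects the rows misclassified in the requested clinical direction and
#' tabulates the requested features' values together with their arithmetic
#' mean. Directions follow the clinical reading of this package's target
#' coding (`positive` = disease-present label, default 0): a false negative
#' is a disease-present case predicted absent, a false positive the
#' converse.
#'
#' @param ds a [gs_dataset()] (true labels come from `ds$y`).
#' @param y_pred predicted labels aligned with `ds`.
#' @param group `"false_negative"` or `"false_positive"`.
#' @param features 0-based feature indices to profile (default: all).
#' @param positive the disease-present label (default 0).
#' @return data.frame with one row per feature: the misclassified cases'
#'   values (columns named `case_<row>`) and a `mean` column. Empty group
#'   gives a 0-column table, not an error.
#' @export
misclassification_profile <- function(ds, y_pred,
                                      group = c("false_negative",
                                                "false_positive"),
                                      features = NULL, positive = 0L) {
  stopifnot(inherits(ds, "gs_dataset"))
  group <- match.arg(group)
  y_pred <- as.integer(y_pred)
  if (length(y_pred) != nrow(ds$X)) stop("predictions not aligned with dataset")
  if (is.null(features)) features <- ds$schema$index
  rows <- if (group == "false_negative") {
    which(ds$y == positive & y_pred != positive)
  } else {
    which(ds$y != positive & y_pred == positive)
  }
  cols <- match(features, ds$schema$index)
  vals <- ds$X[rows, cols, drop = FALSE]
  casevals <- t(vals)
  out <- as.data.frame(casevals)
  names(out) <- if (length(rows)) paste0("case_", rows) else character(0)
  out <- cbind(data.frame(feature = ds$schema$name[cols], index = features),
               out)
  out$mean <- if (length(rows)) rowMeans(casevals) else NA_real_
  rownames(out) <- NULL
  out
}

#' Maximum-depth overfitting sweep
#'
#' Refits the forest at each depth in `depths` (other hyperparameters from
#' `base`), evaluates both the training and the test slice, and reports the
#' train-minus-test accuracy gap — the diagnostic showing how deep trees
#' memorize the training data while test accuracy saturates.
#'
#' @param X_train,y_train,X_test,y_test train and test slices.
#' @param depths integer depths to sweep (default 1:20).
#' @param base a [gs_candidate()] supplying features and the non-depth
#'   hyperparameters.
#' @param seed forest seed (the table is deterministic given it).
#' @param positive positive label for the metrics.
#' @return data.frame with per-depth train/test accuracy, F1, precision,
#'   recall and `gap_pct` (train minus test accuracy, percentage points).
#' @export
depth_sweep <- function(X_train, y_train, X_test, y_test, depths = 1:20,
                        base, seed = 1L, positive = 1L) {
  if (!length(depths)) stop("depths must be non-empty")
  rows <- lapply(depths, function(d) {
    cand <- gs_candidate(base$features,
                         c(base$phi[["n_trees"]], d,
                           base$phi[["min_split"]], base$phi[["min_leaf"]]))
    fit <- fit_forest(X_train, y_train, cand, seed)
    mtr <- classification_metrics(confusion_counts(
      y_train, predict(fit, X_train), positive))
    mte <- classification_metrics(confusion_counts(
      y_test, predict(fit, X_test), positive))
    data.frame(depth = d,
               train_accuracy = mtr$accuracy, train_f1 = mtr$f1,
               test_accuracy = mte$accuracy, test_f1 = mte$f1,
               gap_pct = 100 * (mtr$accuracy - mte$accuracy))
  })
  do.call(rbind, rows)
}

#' Assemble a dataset from a long misclassified-case table
#'
#' Rebuilds a [gs_dataset()] plus an aligned prediction vector from a long
#' table with columns `group` (`false_negative` / `false_positive`),
#' `feature` (schema feature name), `case` (case identifier) and `value` —
#' the plain-text form in which worked-example misclassification profiles
#' ship under `inst/extdata/`. False negatives get true label `positive`
#' and the opposite prediction; false positives the converse. Features not
#' present in the table are filled with zeros.
#'
#' @param df data.frame in the long format above, or a path to such a CSV.
#' @param schema feature schema.
#' @param positive disease-present label (default 0).
#' @return A list with `ds` (the dataset), `y_pred` (predictions) and
#'   `cases` (case id per row).
#' @export
cases_to_dataset <- function(df, schema = gallstone_schema(), positive = 0L) {
  if (is.character(df)) df <- utils::read.csv(df, stringsAsFactors = FALSE)
  stopifnot(all(c("group", "feature", "case", "value") %in% names(df)))
  df$key <- paste(df$group, df$case)
  keys <- unique(df$key)
  X <- matrix(0, length(keys), nrow(schema))
  for (i in seq_along(keys)) {
    sub <- df[df$key == keys[i], ]
    cols <- match(sub$feature, schema$name)
    if (anyNA(cols)) {
      stop("unknown feature name(s): ",
           paste(unique(sub$feature[is.na(cols)]), collapse = ", "))
    }
    X[i, cols] <- sub$value
  }
  grp <- df$group[match(keys, df$key)]
  negative <- 1L - positive
  y_true <- ifelse(grp == "false_negative", positive, negative)
  y_pred <- ifelse(grp == "false_negative", negative, positive)
  list(ds = gs_dataset(X, y_true, schema), y_pred = as.integer(y_pred),
       cases = df$case[match(keys, df$key)])
}
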