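#' Joint feature-subset / hyperparameter search space
#'
#' The optimizer's position vector has `5 + n_features` dimensions: four
#' integer forest hyperparameters, a feature-count dial, and one continuous
#' saliency value per feature in `[0, 1]`:
#' \describe{
#'   \item{phi1}{number of trees, 100-300}
#'   \item{phi2}{maximum tree depth, 3-10}
#'   \item{phi3}{minimum samples to split a node, 2-20}
#'   \item{phi4}{minimum samples per leaf, 1-10}
#'   \item{phi5}{number of selected features, 1 to `n_features`}
#' }
#'
#' @param n_features number of candidate features.
#' @return A list of class `gs_search_space` with `lower`/`upper` bound
#'   vectors and the stored `n_features`.
#' @export
search_space <- function(n_features = 38L) {
  n_features <- as.integer(n_features)
  stopifnot(n_features >= 1L)
  structure(list(
    lower = c(100, 3, 2, 1, 1, rep(0, n_features)),
    upper = c(300, 10, 20, 10, n_features, rep(1, n_features)),
    n_features = n_features
  ), class = "gs_search_space")
}

round_half_up <- function(x) floor(x + 0.5)

#' Decode an optimizer position into a candidate solution
#'
#' The five leading coordinates are rounded half-up and clamped to their
#' integer ranges; the feature subset is the `phi5` features with the
#' largest saliency values, ties broken by the lowest feature index.
#' Deterministic and total on the bounded box.
#'
#' @param position numeric vector of length `5 + n_features`.
#' @param space a [search_space()].
#' @return A list of class `gs_candidate` with `features` (sorted 0-based
#'   indices) and `phi` (named integer vector `n_trees`, `max_depth`,
#'   `min_split`, `min_leaf`).
#' @export
decode_position <- function(position, space) {
  stopifnot(length(position) == 5L + space$n_features)
  ints <- round_half_up(position[1:5])
  ints <- pmin(pmax(ints, space$lower[1:5]), space$upper[1:5])
  k <- as.integer(ints[5])
  sal <- position[-(1:5)]
  sel <- order(-sal, seq_along(sal))[seq_len(k)]
  gs_candidate(sort(sel) - 1L, ints[1:4])
}

#' Construct a candidate solution
#'
#' @param features sorted 0-based feature indices.
#' @param phi four integers: number of trees, max depth, min samples to
#'   split, min samples per leaf.
#' @return A `gs_candidate`.
#' @export
gs_candidate <- function(features, phi) {
  features <- sort(unique(as.integer(features)))
  if (length(features) < 1L) stop("a candidate must select >= 1 feature")
  phi <- as.integer(phi)
  stopifnot(length(phi) == 4L)
  names(phi) <- c("n_trees", "max_depth", "min_split", "min_leaf")
  structure(list(features = features, phi = phi), class = "gs_candidate")
}

#' @export
print.gs_candidate <- function(x, ...) {
  cat(sprintf("<gs_candidate> %d features {%s}; trees=%d depth=%d split=%d leaf=%d\n",
              length(x$features), paste(x$features, collapse = ","),
              x$phi[1], x$phi[2], x$phi[3], x$phi[4]))
  invisible(x)
}

#' Train the delegated random forest for a candidate
#'
#' Fits a Gini-criterion probability forest (via \pkg{ranger}) on the
#' candidate's feature subset with its four hyperparameters and a fixed
#' seed, so training is deterministic within a run.
#'
#' @param X numeric feature matrix (all features; the candidate picks its
#'   columns).
#' @param y 0/1 label vector with at least one sample of each class.
#' @param candidate a [gs_candidate()].
#' @param seed integer seed for the forest.
#' @return An object of class `gs_forest` wrapping the fit; use
#'   [predict.gs_forest()] for class labels or positive-class
#'   probabilities.
#' @export
fit_forest <- function(X, y, candidate, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("training error: training slice contains a single class")
  }
  cols <- candidate$features + 1L
  if (any(cols < 1L | cols > ncol(X))) stop("candidate feature index out of range")
  Xs <- X[, cols, drop = FALSE]
  colnames(Xs) <- paste0("f", candidate$features)
  fit <- ranger::ranger(
    x = Xs, y = factor(y, levels = c(0, 1)),
    num.trees = candidate$phi[["n_trees"]],
    max.depth = candidate$phi[["max_depth"]],
    min.node.size = candidate$phi[["min_split"]],
    min.bucket = candidate$phi[["min_leaf"]],
    splitrule = "gini", probability = TRUE,
    num.threads = 1L, seed = seed, verbose = FALSE
  )
  structure(list(fit = fit, candidate = candidate, seed = seed),
            class = "gs_forest")
}

#' Predict from a fitted candidate forest
#'
#' @param object a `gs_forest`.
#' @param newdata numeric matrix with the full feature set as columns (the
#'   model extracts its own subset).
#' @param type `"class"` for 0/1 labels or `"prob"` for the probability of
#'   the positive class (label 1, "absence").
#' @param ... unused.
#' @return Integer labels or a numeric probability vector.
#' @export
predict.gs_forest <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  cols <- object$candidate$features + 1L
  Xs <- newdata[, cols, drop = FALSE]
  colnames(Xs) <- paste0("f", object$candidate$features)
  p <- unname(stats::predict(object$fit, data = Xs,
                             num.threads = 1L)$predictions[, "1"])
  if (type == "prob") p else as.integer(p > 0.5)
}

#' @export
print.gs_forest <- function(x, ...) {
  cat("<gs_forest> "); print(x$candidate); invisible(x)
}

#' Candidate fitness by F1-score
#'
#' Trains the candidate's forest and scores it with the F1-score of the
#' positive class. The default `"train_f1"` mode scores on the same
#' training slice the forest was fitted on, which is the behaviour of the
#' reference pipeline (its fitness saturates at 1 almost immediately);
#' `"holdout_f1"` scores on an inner stratified 80/20 split and is provided
#' because the training-set score stops discriminating once saturated.
#'
#' @param X,y training slice.
#' @param candidate a [gs_candidate()].
#' @param seed forest seed (and inner-split seed in holdout mode).
#' @param mode `"train_f1"` (default) or `"holdout_f1"`.
#' @return A list of class `gs_fitness` with `candidate` and `fitness`.
#' @export
candidate_fitness <- function(X, y, candidate, seed = 1L,
                              mode = c("train_f1", "holdout_f1")) {
  mode <- match.arg(mode)
  y <- as.integer(y)
  if (mode == "train_f1") {
    model <- fit_forest(X, y, candidate, seed)
    pred <- predict(model, X, type = "class")
    f1 <- f1_score(y, pred, positive = 1L)
  } else {
    inner <- make_splits(y, n_splits = 1L, train_fraction = 0.8, seed = seed)
    tr <- inner[[1]]$train; te <- inner[[1]]$test
    model <- fit_forest(X[tr, , drop = FALSE], y[tr], candidate, seed)
    pred <- predict(model, X[te, , drop = FALSE], type = "class")
    f1 <- f1_score(y[te], pred, positive = 1L)
  }
  structure(list(candidate = candidate, fitness = f1), class = "gs_fitness")
}

# F1 with the degenerate 0/0 case scored 0 (no true positives predicted
# or present), so a swarm of poor candidates still gets a finite score.
f1_score <- function(y_true, y_pred, positive = 1L) {
  cc <- confusion_counts(y_true, y_pred, positive = positive)
  denom <- 2 * cc[["tp"]] + cc[["fp"]] + cc[["fn"]]
  if (denom == 0) return(0)
  2 * cc[["tp"]] / denom
}

#' Optimize one training fold
#'
#' Runs the sand cat swarm over the joint feature-subset / hyperparameter
#' space, evaluating candidates by [candidate_fitness()] on the fold's
#' training slice only (the fold's test rows are never seen). Decoded
#' candidates are memoised within the fold, and because F1 is bounded by 1
#' the search stops as soon as the recorded best reaches that ceiling
#' (ties never replace the first best found, so the result is unchanged).
#'
#' @param X,y the fold's training slice.
#' @param space a [search_space()] for `ncol(X)` features.
#' @param control an [scso_control()]; its `target_fitness` defaults to 1.
#' @param mode fitness mode, see [candidate_fitness()].
#' @param model_seed seed for every forest fit in this fold.
#' @return A list of class `gs_fold` with `candidate`, `fitness`, `history`
#'   and `evaluations`.
#' @export
optimize_fold <- function(X, y, space = search_space(ncol(X)),
                          control = scso_control(), mode = "train_f1",
                          model_seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("training error: constant labels; nothing to optimize")
  }
  if (is.null(control$target_fitness)) control$target_fitness <- 1
  memo <- new.env(parent = emptyenv())
  fn <- function(position) {
    cand <- decode_position(position, space)
    key <- paste(c(cand$phi, cand$features), collapse = ",")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    v <- candidate_fitness(X, y, cand, seed = model_seed, mode = mode)$fitness
    memo[[key]] <- v
    v
  }
  res <- scso_optimize(fn, space$lower, space$upper, control)
  structure(list(candidate = decode_position(res$par, space),
                 fitness = res$value, history = res$history,
                 evaluations = res$evaluations,
                 converged_at = res$converged_at),
            class = "gs_fold")
}

#' @export
print.gs_fold <- function(x, ...) {
  cat(sprintf("<gs_fold> fitness %.4f; ", x$fitness)); print(x$candidate)
  invisible(x)
}

#' Serialize a candidate solution to JSON
#'
#' @param candidate a [gs_candidate()] (or `gs_fold` / `gs_fitness`).
#' @param path output path.
#' @param fitness optional fitness value to include.
#' @return `path`, invisibly.
#' @export
write_candidate_json <- function(candidate, path, fitness = NULL) {
  if (inherits(candidate, c("gs_fold", "gs_fitness"))) {
    fitness <- candidate$fitness
    candidate <- candidate$candidate
  }
  jsonlite::write_json(
    list(features = candidate$features, phi = unname(candidate$phi),
         fitness = fitness),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
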