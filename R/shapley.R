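#' Probability accessor for explainable models
#'
#' The interpretability functions are model-agnostic: anything with a
#' `predict_prob` method (returning the positive-class probability for each
#' row of a matrix) can be explained. Methods ship for [fit_forest()]
#' models and for plain functions `f(X) -> probabilities`.
#'
#' @param model the model.
#' @param X numeric matrix, full feature set as columns.
#' @return Numeric vector of probabilities, one per row.
#' @export
predict_prob <- function(model, X) UseMethod("predict_prob")

#' @export
predict_prob.gs_forest <- function(model, X) predict(model, X, type = "prob")

#' @export
predict_prob.function <- function(model, X) {
  as.numeric(model(as.matrix(X)))
}

#' Interventional value function of a feature subset
#'
#' The model output attributed to a subset `R` of features: every
#' background row has its `R` columns overwritten by the explained
#' instance's values, and the model probability is averaged over the
#' (modified) background. `R = all features` gives the model output at the
#' instance; `R = {}` gives the base value (the mean background output).
#'
#' @param model a model with a [predict_prob()] method.
#' @param instance numeric feature vector.
#' @param subset 0-based feature indices (may be empty).
#' @param background numeric matrix of background rows (non-empty).
#' @return Mean model probability.
#' @export
shap_value_function <- function(model, instance, subset, background) {
  background <- as.matrix(background)
  if (nrow(background) == 0L) stop("background must be non-empty")
  if (length(subset)) {
    cols <- as.integer(subset) + 1L
    background[, cols] <- matrix(instance[cols], nrow(background),
                                 length(cols), byrow = TRUE)
  }
  mean(predict_prob(model, background))
}

#' Exact Shapley attribution by subset enumeration
#'
#' Computes the Shapley value of each feature in `features` by the full
#' weighted sum over subsets `R` of the remaining features,
#' `sum_R |R|! (g - |R| - 1)! / g! * (v(R + j) - v(R))`, with the
#' interventional value function of [shap_value_function()]. Exact, so the
#' efficiency identity `base_value + sum(phi) = prediction` holds to
#' numerical precision; enumeration is exponential and guarded at 16
#' features.
#'
#' @param model a model with a [predict_prob()] method.
#' @param instance numeric feature vector (full feature set).
#' @param background background matrix; by convention a (seeded, capped)
#'   subsample of the training slice.
#' @param features 0-based indices of the features to attribute (the
#'   model's feature set). At most 16.
#' @return An object of class `gs_shapley`: list with `base_value`, `phi`
#'   (named per feature), `prediction`, `predicted_class` (1 if the
#'   prediction exceeds 0.5, else 0), `instance` and `features`.
#' @export
exact_shapley <- function(model, instance, background, features) {
  features <- as.integer(features)
  g <- length(features)
  if (g > 16L) {
    stop("exact enumeration guarded at 16 features; use a sampling ",
         "approximation for larger sets")
  }
  background <- as.matrix(background)
  n_subsets <- bitwShiftL(1L, g)
  # cache v(R) for every subset mask, batching model calls over chunks of
  # masks to keep predict overhead off the critical path
  v <- numeric(n_subsets)
  b <- nrow(background)
  chunk <- max(1L, 65536L %/% b)
  masks <- 0:(n_subsets - 1)
  for (start in seq(1L, n_subsets, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_subsets)
    big <- do.call(rbind, lapply(masks[idx], function(m) {
      bg <- background
      on <- features[bitwAnd(bitwShiftR(m, 0:(g - 1)), 1L) == 1L]
      if (g == 0L) on <- integer(0)
      if (length(on)) {
        cols <- on + 1L
        bg[, cols] <- matrix(instance[cols], b, length(cols), byrow = TRUE)
      }
      bg
    }))
    p <- predict_prob(model, big)
    v[idx] <- colMeans(matrix(p, nrow = b))
  }
  lf <- lgamma(seq_len(g + 1))        # lgamma(k+1) = log(k!)
  wt <- function(r) exp(lf[r + 1] + lf[g - r] - lf[g + 1])
  phi <- numeric(g)
  for (ji in seq_len(g)) {
    jbit <- bitwShiftL(1L, ji - 1L)
    rest <- masks[bitwAnd(masks, jbit) == 0L]
    sizes <- vapply(rest, function(m) sum(bitwAnd(bitwShiftR(m, 0:(g - 1)), 1L)),
                    numeric(1))
    phi[ji] <- sum(wt(sizes) * (v[rest + jbit + 1L] - v[rest + 1L]))
  }
  names(phi) <- paste0("f", features)
  prediction <- v[n_subsets]
  structure(list(base_value = v[1L], phi = phi, prediction = prediction,
                 predicted_class = as.integer(prediction > 0.5),
                 instance = instance, features = features),
            class = "gs_shapley")
}

#' @export
print.gs_shapley <- function(x, digits = 4, ...) {
  cat(sprintf("<gs_shapley> base %.4f -> prediction %.4f (class %d)\n",
              x$base_value, x$prediction, x$predicted_class))
  print(round(sort(x$phi, decreasing = TRUE), digits))
  invisible(x)
}

#' Mean absolute Shapley ranking
#'
#' Global importance ranking: the mean of `|phi_j|` across a set of
#' explanations on a common feature set, sorted descending.
#'
#' @param explanations list of `gs_shapley` objects sharing one feature
#'   set.
#' @return data.frame with `index` (0-based), `mean_abs_phi`, sorted
#'   descending.
#' @export
mean_abs_shapley <- function(explanations) {
  if (!length(explanations)) stop("need >= 1 explanation")
  feats <- explanations[[1]]$features
  same <- vapply(explanations, function(e) identical(e$features, feats),
                 logical(1))
  if (!all(same)) stop("explanations use mixed feature sets")
  phi_mat <- do.call(rbind, lapply(explanations, `[[`, "phi"))
  out <- data.frame(index = feats, mean_abs_phi = colMeans(abs(phi_mat)))
  out <- out[order(-out$mean_abs_phi), ]
  rownames(out) <- NULL
  out
}

#' Serialize an explanation to JSON
#'
#' @param explanation a `gs_shapley`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_shapley_json <- function(explanation, path) {
  jsonlite::write_json(
    list(base_value = explanation$base_value,
         phi = as.list(explanation$phi),
         prediction = explanation$prediction,
         predicted_class = explanation$predicted_class),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
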