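#' Specify a counterfactual query
#'
#' Describes what to search for: the instance to perturb, the target class
#' the model should be flipped to, how many counterfactuals, which features
#' may change (the actionable set), their admissible ranges, and the
#' proximity/diversity trade-off weights.
#'
#' @param instance numeric feature vector (full feature set).
#' @param target_class 0 or 1.
#' @param k number of counterfactuals (>= 1).
#' @param actionable non-empty 0-based indices of features allowed to
#'   change. For the gallstone model the natural default is the three
#'   dominant labs CRP, Vitamin D and AAST (indices 35, 37, 30).
#' @param ranges numeric matrix with rows `min`/`max` and one column per
#'   actionable feature (in `actionable` order): the admissible search box.
#' @param lambda1 proximity weight (default 0.5).
#' @param lambda2 diversity weight (default 1.0).
#' @return A list of class `gs_cf_query`.
#' @export
cf_query <- function(instance, target_class, k = 4L,
                     actionable = c(35L, 37L, 30L), ranges,
                     lambda1 = 0.5, lambda2 = 1.0) {
  stopifnot(k >= 1L, length(actionable) >= 1L, lambda1 >= 0, lambda2 >= 0)
  ranges <- as.matrix(ranges)
  if (nrow(ranges) != 2L || ncol(ranges) != length(actionable)) {
    stop("ranges must be a 2 x length(actionable) matrix (min; max)")
  }
  if (any(ranges[1, ] > ranges[2, ])) stop("ranges must satisfy min <= max")
  structure(list(instance = instance, target_class = as.integer(target_class),
                 k = as.integer(k), actionable = as.integer(actionable),
                 ranges = ranges, lambda1 = lambda1, lambda2 = lambda2),
            class = "gs_cf_query")
}

# median-absolute-deviation scale per feature, computed on training data;
# zero MADs fall back to 1 so binary/constant features stay comparable
mad_scale <- function(X) {
  s <- apply(as.matrix(X), 2, stats::mad)
  s[s == 0 | !is.finite(s)] <- 1
  s
}

cf_distance <- function(candidate, instance, scale, actionable) {
  cols <- actionable + 1L
  mean(abs(candidate[cols] - instance[cols]) / scale[cols])
}

# DPP diversity: log-determinant of K_ij = 1 / (1 + dist(c_i, c_j)),
# determinant floored before the log so duplicate candidates degrade
# gracefully instead of diverging
dpp_diversity <- function(cands, scale, actionable) {
  k <- nrow(cands)
  K <- matrix(1, k, k)
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      d <- cf_distance(cands[i, ], cands[j, ], scale, actionable)
      K[i, j] <- K[j, i] <- 1 / (1 + d)
    }
  }
  log(max(det(K), 1e-12))
}

# hinge loss on the probability margin to the target class:
# 0 when the model is certain of the target, 1 at the decision boundary
cf_yloss <- function(p_target) pmax(0, 1 - (2 * p_target - 1))

#' Counterfactual set objective
#'
#' The score a candidate set is optimized under: mean hinge classification
#' loss towards the target class, plus `lambda1` times the mean
#' MAD-weighted L1 distance to the original instance (over actionable
#' features), minus `lambda2` times the determinantal-point-process
#' diversity (log-determinant of the similarity kernel
#' `K_ij = 1 / (1 + dist(c_i, c_j))`). Lower is better; the diversity term
#' is invariant to the candidate order.
#'
#' @param cands numeric matrix, one candidate per row (full feature set).
#' @param query a [cf_query()].
#' @param model model with a [predict_prob()] method.
#' @param scale per-feature MAD scale vector (see `training` in
#'   [generate_counterfactuals()]).
#' @return A list with `total`, `mean_yloss`, `mean_dist`, `diversity`.
#' @export
cf_objective <- function(cands, query, model, scale) {
  cands <- as.matrix(cands)
  p1 <- predict_prob(model, cands)
  p_target <- if (query$target_class == 1L) p1 else 1 - p1
  yloss <- mean(cf_yloss(p_target))
  dist <- mean(apply(cands, 1, cf_distance, instance = query$instance,
                     scale = scale, actionable = query$actionable))
  div <- dpp_diversity(cands, scale, query$actionable)
  list(total = yloss + query$lambda1 * dist - query$lambda2 * div,
       mean_yloss = yloss, mean_dist = dist, diversity = div)
}

#' Generate diverse counterfactuals by swarm search
#'
#' Searches the concatenated `k x length(actionable)` perturbation space
#' with the sand cat swarm, minimizing [cf_objective()]. Only actionable
#' coordinates ever differ from the original instance, and every candidate
#' stays within the query's ranges. Candidates whose predicted class equals
#' the target are flagged valid; if fewer than `k` are valid the remaining
#' best-effort near-misses are kept but flagged invalid.
#'
#' @param model model with a [predict_prob()] method.
#' @param query a [cf_query()].
#' @param training numeric matrix of training rows used to compute the
#'   MAD proximity scale.
#' @param control an [scso_control()] for the search (give it a seed for
#'   reproducibility).
#' @return An object of class `gs_counterfactuals`: list with `candidates`
#'   (matrix, k rows), `predicted_class`, `prob_target`, `valid` (logical),
#'   `dist` (per candidate), `objective` (final [cf_objective()] breakdown)
#'   and the `query`. Zero valid candidates is reported via the `valid`
#'   flags and a diagnostic message, not an error.
#' @export
generate_counterfactuals <- function(model, query, training,
                                     control = scso_control(pop_size = 30L,
                                                            max_iter = 40L)) {
  stopifnot(inherits(query, "gs_cf_query"))
  scale <- mad_scale(training)
  na <- length(query$actionable)
  lower <- rep(query$ranges[1, ], times = query$k)
  upper <- rep(query$ranges[2, ], times = query$k)
  decode <- function(position) {
    cands <- matrix(query$instance, nrow = query$k,
                    ncol = length(query$instance), byrow = TRUE)
    pert <- matrix(position, nrow = query$k, ncol = na, byrow = TRUE)
    cands[, query$actionable + 1L] <- pert
    cands
  }
  res <- scso_optimize(function(position) {
    -cf_objective(decode(position), query, model, scale)$total
  }, lower, upper, control)
  cands <- decode(res$par)
  p1 <- predict_prob(model, cands)
  pred <- as.integer(p1 > 0.5)
  p_target <- if (query$target_class == 1L) p1 else 1 - p1
  valid <- pred == query$target_class
  if (!any(valid)) {
    message("no valid counterfactual found within the search budget; ",
            "returning near-misses flagged invalid")
  }
  ord <- order(!valid, -p_target)   # valid first, then by target confidence
  cands <- cands[ord, , drop = FALSE]
  structure(list(candidates = cands,
                 predicted_class = pred[ord],
                 prob_target = p_target[ord],
                 valid = valid[ord],
                 dist = apply(cands, 1, cf_distance,
                              instance = query$instance, scale = scale,
                              actionable = query$actionable),
                 objective = cf_objective(cands, query, model, scale),
                 query = query),
            class = "gs_counterfactuals")
}

#' @export
print.gs_counterfactuals <- function(x, ...) {
  cat(sprintf("<gs_counterfactuals> %d candidates (%d valid) -> class %d\n",
              nrow(x$candidates), sum(x$valid), x$query$target_class))
  invisible(x)
}

#' Tabulate counterfactuals as original -> changed values
#'
#' Renders a counterfactual set as a table with one row per candidate and,
#' for each actionable feature, the original value and its replacement,
#' plus the class flip column.
#'
#' @param cf a `gs_counterfactuals`.
#' @param schema feature schema used for column names.
#' @return data.frame.
#' @export
cf_table <- function(cf, schema = gallstone_schema()) {
  q <- cf$query
  nm <- schema$name[match(q$actionable, schema$index)]
  out <- data.frame(serial = seq_len(nrow(cf$candidates)))
  for (i in seq_along(q$actionable)) {
    col <- q$actionable[i] + 1L
    orig <- q$instance[col]
    new <- cf$candidates[, col]
    out[[nm[i]]] <- ifelse(abs(new - orig) < 1e-9,
                           sprintf("%.2f", orig),
                           sprintf("%.2f -> %.2f", orig, new))
  }
  out$predicted_class <- cf$predicted_class
  out$valid <- cf$valid
  out
}
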