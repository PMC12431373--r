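#' Union of fold-selected features
#'
#' The final feature set keeps any feature selected in at least one fold:
#' the sorted union, without duplicates, of the fold subsets.
#'
#' @param outcomes list of fold outcomes (`gs_fold`, `gs_candidate`, or
#'   plain lists with a `features` element of 0-based indices).
#' @return Sorted integer vector of 0-based feature indices.
#' @export
union_features <- function(outcomes) {
  outcomes <- normalize_outcomes(outcomes)
  sort(unique(unlist(lapply(outcomes, `[[`, "features"))))
}

#' Per-parameter mode of fold hyperparameters
#'
#' Majority vote across folds, applied to each of the four forest
#' hyperparameters independently: the most frequent value wins; ties are
#' broken by the smallest value, which makes the result deterministic and
#' invariant to fold order.
#'
#' @inheritParams union_features
#' @return Named integer vector (`n_trees`, `max_depth`, `min_split`,
#'   `min_leaf`).
#' @export
mode_hyperparams <- function(outcomes) {
  outcomes <- normalize_outcomes(outcomes)
  phi_mat <- do.call(rbind, lapply(outcomes, function(o) as.integer(o$phi)))
  stopifnot(ncol(phi_mat) == 4L)
  phi <- apply(phi_mat, 2, function(v) {
    tab <- table(v)
    winners <- as.integer(names(tab)[tab == max(tab)])
    min(winners)
  })
  names(phi) <- c("n_trees", "max_depth", "min_split", "min_leaf")
  phi
}

#' Consolidate fold outcomes into a final configuration
#'
#' Combines per-fold optimization results into one deployable
#' configuration: feature union plus per-parameter hyperparameter mode.
#'
#' @inheritParams union_features
#' @return A [gs_candidate()] carrying the consolidated features and
#'   hyperparameters.
#' @export
consolidate_folds <- function(outcomes) {
  gs_candidate(union_features(outcomes), mode_hyperparams(outcomes))
}

normalize_outcomes <- function(outcomes) {
  if (length(outcomes) < 1L) stop("parameter error: need >= 1 fold outcome")
  lapply(outcomes, function(o) {
    if (inherits(o, "gs_fold")) o <- o$candidate
    if (is.null(o$features) || is.null(o$phi)) {
      stop("each outcome needs 'features' and 'phi'")
    }
    o
  })
}

#' Read fold outcomes from a plain CSV table
#'
#' Parses a fold table with columns `fold`, `features` (semicolon-separated
#' 0-based indices), `phi1`..`phi4` — the on-disk form used for worked
#' examples and pipeline artifacts.
#'
#' @param path CSV path.
#' @return List of outcomes suitable for [consolidate_folds()].
#' @export
read_fold_outcomes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    list(features = as.integer(strsplit(df$features[i], ";")[[1]]),
         phi = c(df$phi1[i], df$phi2[i], df$phi3[i], df$phi4[i]))
  })
}
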