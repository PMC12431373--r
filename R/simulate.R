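#' Specification for a synthetic gallstone-schema dataset
#'
#' Describes a class-conditionally generated 38-feature table emulating the
#' gallstone screening schema: a handful of signal features drawn with
#' different means per class, everything else class-independent noise with
#' plausible clinical ranges. The default signal triple is the three
#' dominant labs with their observed class means — CRP 0.46 (present) vs
#' 3.27 (absent), modeled lognormal (non-negative, right-skewed); Vitamin D
#' 24.90 vs 17.83 and AAST 23.91 vs 19.41, modeled normal truncated at 0.
#' Spreads (sdlog 0.75; sd 8 and 7) are chosen to give realistic lab
#' variability with moderate class overlap.
#'
#' @param n_samples total rows (default 319).
#' @param class_counts two integers summing to `n_samples`: disease-present
#'   (label 0) and absent (label 1) counts; default `c(161, 158)`.
#' @param signal named list, one entry per signal feature (names must be
#'   schema feature names), each a list with `mean0`, `mean1`, `sd`,
#'   `dist` (`"normal"` or `"lognormal"`; for lognormal, `sd` is the
#'   log-scale sd and the means are arithmetic). An empty list gives an
#'   all-noise null dataset.
#' @param seed integer RNG seed.
#' @return A list of class `gs_sim_spec`.
#' @export
synthetic_spec <- function(n_samples = 319L,
                           class_counts = c(161L, 158L),
                           signal = list(
                             "CRP" = list(mean0 = 0.46, mean1 = 3.27,
                                          sd = 0.75, dist = "lognormal"),
                             "Vitamin D" = list(mean0 = 24.90, mean1 = 17.83,
                                                sd = 8, dist = "normal"),
                             "AAST" = list(mean0 = 23.91, mean1 = 19.41,
                                           sd = 7, dist = "normal")
                           ),
                           seed = 1L) {
  if (sum(class_counts) != n_samples) {
    stop("class_counts must sum to n_samples")
  }
  sch <- gallstone_schema()
  bad <- setdiff(names(signal), sch$name)
  if (length(bad)) stop("unknown signal feature(s): ", paste(bad, collapse = ", "))
  for (s in signal) {
    if (!s$dist %in% c("normal", "lognormal")) {
      stop("invalid distribution name: ", s$dist)
    }
    if (s$sd <= 0) stop("signal sds must be > 0")
  }
  structure(list(n_samples = as.integer(n_samples),
                 class_counts = as.integer(class_counts),
                 signal = signal, seed = as.integer(seed)),
            class = "gs_sim_spec")
}

# class-independent noise models per schema feature, loosely matching the
# clinical ranges of each measurement; binary flags are low-prevalence
# comorbidities, categoricals small codes
noise_column <- function(kind, name, n) {
  switch(kind,
    binary = stats::rbinom(n, 1, switch(name, CAD = 0.08, Hypothyroidism = 0.1,
                                        Hyperlipidemia = 0.2, DM = 0.15, 0.15)),
    categorical = sample(0:2, n, replace = TRUE,
                         prob = c(0.5, 0.3, 0.2)),
    integer = switch(name,
      Age = sample(20:75, n, replace = TRUE),
      Height = sample(145:195, n, replace = TRUE),
      VFR = sample(1:20, n, replace = TRUE),
      sample(0:100, n, replace = TRUE)),
    continuous = {
      base <- switch(name,
        Weight = c(78, 15), BMI = c(27, 5), TBW = c(40, 7), ECW = c(16, 3),
        ICW = c(24, 5), "ECF/TBW" = c(0.39, 0.02), TBFR = c(30, 8),
        LM = c(55, 10), Protein = c(16, 2), BM = c(2.9, 0.5), MM = c(52, 9),
        Obesity = c(30, 15), TFC = c(25, 10), VFA = c(120, 40),
        VMA = c(100, 20), Glucose = c(100, 20), TC = c(200, 35),
        LDL = c(130, 30), HDL = c(50, 12), Triglyceride = c(140, 60),
        AAST = c(22, 7), ALT = c(25, 12), ALP = c(80, 22),
        Creatinine = c(0.85, 0.2), GFR = c(95, 15), CRP = c(1.5, 1.5),
        HGB = c(14, 1.5), "Vitamin D" = c(21, 8), c(0, 1))
      pmax(stats::rnorm(n, base[1], base[2]), 0)
    },
    stop("unknown feature kind: ", kind))
}

#' Generate a synthetic gallstone-schema dataset
#'
#' Emits a 38-column table honoring the schema's type mix, with labels at
#' the requested class balance, signal features drawn class-conditionally
#' per `spec` and every other column class-independent noise. Rows are
#' shuffled. Fully seeded: the same spec yields a byte-identical dataset.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `dataset` (a [gs_dataset()]) and `manifest`
#'   (signal feature names and 0-based indices, class counts, seed).
#' @export
simulate_gallstone <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "gs_sim_spec"))
  sch <- gallstone_schema()
  n <- spec$n_samples
  if (n < 1L) stop("parameter error: n_samples must be >= 1")
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)
  y <- rep(c(0L, 1L), times = spec$class_counts)
  X <- matrix(0, n, nrow(sch))
  for (j in seq_len(nrow(sch))) {
    X[, j] <- noise_column(sch$kind[j], sch$name[j], n)
  }
  for (nm in names(spec$signal)) {
    s <- spec$signal[[nm]]
    j <- match(nm, sch$name)
    mu <- ifelse(y == 0L, s$mean0, s$mean1)
    X[, j] <- if (s$dist == "lognormal") {
      # arithmetic mean mu with log-scale sd: meanlog = log(mu) - sd^2 / 2
      stats::rlnorm(n, meanlog = log(mu) - s$sd^2 / 2, sdlog = s$sd)
    } else {
      pmax(stats::rnorm(n, mean = mu, sd = s$sd), 0)
    }
  }
  ord <- sample.int(n)
  ds <- gs_dataset(X[ord, , drop = FALSE], y[ord], sch)
  sig_idx <- sch$index[match(names(spec$signal), sch$name)]
  list(dataset = ds,
       manifest = list(signal_features = names(spec$signal),
                       signal_indices = as.integer(sig_idx),
                       class_counts = spec$class_counts,
                       n_samples = n, seed = spec$seed))
}

#' Planted-signal recovery harness
#'
#' Runs the full optimize-and-consolidate pipeline on synthetic data with
#' known informative features, once per seed, and reports how often the
#' consolidated feature union recovers the planted signal. This is the
#' package's end-to-end sanity experiment: the union consolidation should
#' retain every informative feature across repeated runs.
#'
#' @param spec a [synthetic_spec()] (its seed is replaced per run).
#' @param seeds integer vector of run seeds.
#' @param n_splits splits per run (default 10).
#' @param control an [scso_control()] for the per-fold search.
#' @param holdout_metrics if TRUE, also fit the consolidated configuration
#'   per split and report mean holdout accuracy.
#' @return A list of class `gs_recovery` with per-seed results
#'   (`recovered`: number of planted features in the union, `union_size`,
#'   optionally `holdout_accuracy`), and the summary fractions
#'   `all_recovered_fraction` and `mean_recovered_fraction`.
#' @export
planted_recovery <- function(spec = synthetic_spec(),
                             seeds = 1:20,
                             n_splits = 10L,
                             control = scso_control(pop_size = 20L,
                                                    max_iter = 30L),
                             holdout_metrics = FALSE) {
  runs <- lapply(seeds, function(sd) {
    sp <- spec
    sp$seed <- as.integer(sd)
    sim <- simulate_gallstone(sp)
    ds <- sim$dataset
    splits <- make_splits(ds, n_splits = n_splits, seed = sd)
    space <- search_space(ncol(ds$X))
    ctrl <- control
    ctrl$seed <- NULL
    set.seed(sd)
    folds <- lapply(seq_along(splits), function(f) {
      tr <- splits[[f]]$train
      optimize_fold(ds$X[tr, , drop = FALSE], ds$y[tr], space, ctrl,
                    model_seed = sd + f)
    })
    final <- consolidate_folds(folds)
    planted <- sim$manifest$signal_indices
    out <- list(seed = sd,
                union = final$features,
                union_size = length(final$features),
                recovered = sum(planted %in% final$features),
                n_planted = length(planted))
    if (holdout_metrics) {
      acc <- vapply(seq_along(splits), function(f) {
        tr <- splits[[f]]$train; te <- splits[[f]]$test
        fit <- fit_forest(ds$X[tr, , drop = FALSE], ds$y[tr], final,
                          seed = sd + f)
        mean(predict(fit, ds$X[te, , drop = FALSE]) == ds$y[te])
      }, numeric(1))
      out$holdout_accuracy <- mean(acc)
    }
    out
  })
  n_planted <- runs[[1]]$n_planted
  rec <- vapply(runs, `[[`, numeric(1), "recovered")
  structure(list(runs = runs,
                 all_recovered_fraction = mean(rec == n_planted),
                 mean_recovered_fraction = mean(rec / max(n_planted, 1))),
            class = "gs_recovery")
}

#' @export
print.gs_recovery <- function(x, ...) {
  cat(sprintf("<gs_recovery> %d runs; all planted features recovered in %.0f%%\n",
              length(x$runs), 100 * x$all_recovered_fraction))
  invisible(x)
}
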