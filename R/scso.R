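#' Control parameters for a sand cat swarm run
#'
#' @param pop_size number of agents (sand cats); default 50.
#' @param max_iter number of iterations (epochs); default 100.
#' @param sm hearing-sensitivity ceiling; the general sensitivity decays
#'   linearly from `sm` to 0 over the run. Default 2.
#' @param seed integer RNG seed; `NULL` leaves the RNG state untouched.
#' @param target_fitness optional known fitness ceiling. Because ties never
#'   replace the recorded best, once the best fitness reaches this ceiling no
#'   later evaluation can change the returned optimum or the (saturated)
#'   history, so the search stops early. Used by the classifier wrapper,
#'   whose F1 fitness is bounded by 1.
#' @return A list of class `scso_control`.
#' @export
scso_control <- function(pop_size = 50L, max_iter = 100L, sm = 2,
                         seed = NULL, target_fitness = NULL) {
  if (pop_size < 2L) stop("pop_size must be >= 2")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  structure(list(pop_size = as.integer(pop_size),
                 max_iter = as.integer(max_iter),
                 sm = sm, seed = seed, target_fitness = target_fitness),
            class = "scso_control")
}

#' General sensitivity schedule
#'
#' The swarm-wide sensitivity decays linearly from `sm` at iteration 0 to 0
#' at the final iteration: `sm - 2 * sm * tc / (tmax + tmax)`. It shrinks
#' search radii over time and shifts the swarm from exploration to
#' exploitation.
#'
#' @param tc current iteration, `0 <= tc <= tmax`.
#' @param tmax maximum iteration, `>= 1`.
#' @param sm sensitivity ceiling (default 2).
#' @return The sensitivity value in `[0, sm]`.
#' @examples
#' scso_sensitivity(0, 100)   # 2
#' scso_sensitivity(50, 100)  # 1
#' scso_sensitivity(100, 100) # 0
#' @export
scso_sensitivity <- function(tc, tmax, sm = 2) {
  if (tmax < 1) stop("parameter error: tmax must be >= 1")
  sm - 2 * sm * tc / (tmax + tmax)
}

#' Phase-control parameter R
#'
#' Draws `R = 2 * isen * rand - isen` with `rand ~ U(0, 1)`. `|R| <= 1`
#' selects the exploitation (prey attack) branch; `|R| > 1` selects
#' exploration.
#'
#' @param isen current general sensitivity (non-negative).
#' @return A single draw of R.
#' @export
scso_R <- function(isen) 2 * isen * stats::runif(1) - isen

#' Per-agent search radius
#'
#' Each agent gets its own radius `r = isen * rand(0, 1)`, uniform on
#' `[0, isen]`.
#'
#' @param isen current general sensitivity.
#' @return A single radius draw.
#' @export
scso_radius <- function(isen) isen * stats::runif(1)

#' Exploration step
#'
#' Moves an agent relative to the best candidate position:
#' per dimension, `new = r * best - rand(0, 1) * current`, with a fresh
#' uniform draw in every dimension. The caller clamps the result to bounds.
#'
#' @param current current position vector.
#' @param best best candidate position vector (same length).
#' @param r the agent's search radius.
#' @return The proposed position vector.
#' @export
scso_explore <- function(current, best, r) {
  if (length(current) != length(best)) stop("dimension mismatch")
  r * best - stats::runif(length(current)) * current
}

#' Exploitation (prey attack) step
#'
#' Computes `loc_rnd = |rand(0, 1) * best - current|` per dimension (fresh
#' draw each dimension) and pounces at an angle:
#' `new = best - r * loc_rnd * cos(theta)`.
#'
#' @param current current position vector.
#' @param best global best position vector.
#' @param r the agent's search radius.
#' @param theta attack angle in degrees, in `[0, 360]`.
#' @return The proposed position vector.
#' @export
scso_exploit <- function(current, best, r, theta) {
  if (length(current) != length(best)) stop("dimension mismatch")
  loc_rnd <- abs(stats::runif(length(current)) * best - current)
  best - r * loc_rnd * cospi(theta / 180)
}

#' Roulette-wheel attack angle
#'
#' Selects an integer angle in `[0, 360]` degrees by roulette-wheel
#' selection over equal weights, i.e. a uniform marginal over the 361
#' integer degrees.
#'
#' @return An integer angle in degrees.
#' @export
scso_angle <- function() {
  w <- rep(1, 361)
  cum <- cumsum(w) / sum(w)
  # roulette wheel: first slot whose cumulative weight covers the draw
  (findInterval(stats::runif(1), cum, left.open = TRUE)) %% 361L
}

#' Sand Cat Swarm Optimization
#'
#' Maximizes `fn` over a box. A population of agents is initialized
#' uniformly in the bounds and evaluated; each iteration every agent draws
#' its own radius and phase parameter R from the decaying sensitivity
#' schedule, takes an exploration step (towards the best candidate, `|R| >
#' 1`) or an angled exploitation pounce around the global best (`|R| <= 1`),
#' is clamped to the bounds and re-evaluated. The recorded best is elitist:
#' it is replaced only by a strictly better fitness, so the returned history
#' is non-decreasing and ties keep the first solution found.
#'
#' @param fn objective function: numeric vector -> single finite numeric,
#'   maximized.
#' @param lower,upper numeric bound vectors (equal length, `lower <= upper`).
#' @param control an [scso_control()].
#' @return A list of class `scso_result` with elements `par` (best position),
#'   `value` (best fitness), `history` (best fitness after each iteration,
#'   length `max_iter`), `evaluations` (number of objective calls) and
#'   `converged_at` (first iteration at which `target_fitness` was reached,
#'   or `NA`; iteration 0 means the initial population).
#' @examples
#' res <- scso_optimize(function(x) -sum((x - 3)^2), rep(-10, 3), rep(10, 3),
#'                      scso_control(pop_size = 20, max_iter = 50, seed = 1))
#' res$par
#' @export
scso_optimize <- function(fn, lower, upper, control = scso_control()) {
  stopifnot(length(lower) == length(upper), all(lower <= upper),
            all(is.finite(lower)), all(is.finite(upper)))
  d <- length(lower)
  if (!is.null(control$seed)) set.seed(control$seed)
  evaluate <- function(x) {
    v <- tryCatch(fn(x), error = function(e) {
      stop(sprintf("fitness function failed at position [%s]: %s",
                   paste(signif(x, 4), collapse = ", "),
                   conditionMessage(e)))
    })
    if (!is.finite(v)) stop("fitness function returned a non-finite value")
    v
  }
  pos <- matrix(stats::runif(control$pop_size * d), control$pop_size, d)
  pos <- sweep(sweep(pos, 2, upper - lower, "*"), 2, lower, "+")
  fit <- apply(pos, 1, evaluate)
  n_eval <- control$pop_size
  best_i <- which.max(fit)
  best_par <- pos[best_i, ]
  best_val <- fit[best_i]
  tgt <- control$target_fitness
  converged_at <- if (!is.null(tgt) && best_val >= tgt) 0L else NA_integer_
  history <- numeric(control$max_iter)
  for (tc in seq_len(control$max_iter)) {
    if (!is.na(converged_at)) {
      history[tc:control$max_iter] <- best_val
      break
    }
    isen <- scso_sensitivity(tc, control$max_iter, control$sm)
    for (a in seq_len(control$pop_size)) {
      r <- scso_radius(isen)
      R <- scso_R(isen)
      prop <- if (abs(R) <= 1) {
        scso_exploit(pos[a, ], best_par, r, scso_angle())
      } else {
        scso_explore(pos[a, ], best_par, r)
      }
      prop <- pmin(pmax(prop, lower), upper)
      v <- evaluate(prop)
      n_eval <- n_eval + 1L
      pos[a, ] <- prop
      fit[a] <- v
      if (v > best_val) {
        best_val <- v
        best_par <- prop
      }
    }
    history[tc] <- best_val
    if (!is.null(tgt) && best_val >= tgt) converged_at <- tc
  }
  structure(list(par = best_par, value = best_val, history = history,
                 evaluations = n_eval, converged_at = converged_at),
            class = "scso_result")
}

#' @export
print.scso_result <- function(x, ...) {
  cat(sprintf("<scso_result> best fitness %.6g after %d evaluations\n",
              x$value, x$evaluations))
  invisible(x)
}

#' Export a convergence history as CSV
#'
#' @param result an `scso_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_history_csv <- function(result, path) {
  utils::write.csv(
    data.frame(iteration = seq_along(result$history),
               best_fitness = result$history),
    path, row.names = FALSE)
  invisible(path)
}
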