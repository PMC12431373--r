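test_that("general sensitivity decays linearly from sm to 0", {
  expect_equal(scso_sensitivity(0, 100), 2)
  expect_equal(scso_sensitivity(50, 100), 1)
  expect_equal(scso_sensitivity(100, 100), 0)
  for (tmax in c(1, 7, 100)) expect_equal(scso_sensitivity(tmax, tmax), 0)
  # linearity: second differences vanish
  v <- sapply(0:10, scso_sensitivity, tmax = 10, sm = 2)
  expect_equal(diff(v, differences = 2), rep(0, 9))
  expect_error(scso_sensitivity(0, 0), "tmax")
})

test_that("phase parameter R and radius stay within their sensitivity band", {
  set.seed(1)
  expect_equal(scso_R(0), 0)         # terminal iteration forces exploitation
  expect_equal(scso_radius(0), 0)
  r_draws <- replicate(2000, scso_R(2))
  expect_true(all(abs(r_draws) <= 2))
  expect_gt(mean(abs(r_draws) > 1), 0.3)  # both branches occur for isen = 2

  # agent radius is uniform on [0, isen]: Kolmogorov distance < 0.05
  rr <- replicate(1e4, scso_radius(2))
  expect_true(all(rr >= 0 & rr <= 2))
  ks <- max(abs(ecdf(rr)(seq(0, 2, by = 0.01)) - seq(0, 2, by = 0.01) / 2))
  expect_lt(ks, 0.05)
})

test_that("exploration and exploitation steps match their hand formulas", {
  # exploration, 1-D: new = r*best - rand*current; recover the same draw
  set.seed(7); u <- runif(1)
  set.seed(7)
  expect_equal(scso_explore(2, 4, 0.5), 0.5 * 4 - u * 2)
  expect_equal(scso_explore(0, 4, 0), 0)           # r = 0, current = 0
  set.seed(3); u2 <- runif(3)
  set.seed(3)
  expect_equal(scso_explore(c(1, 2, 3), c(4, 5, 6), 1), c(4, 5, 6) - u2 * 1:3)

  # exploitation, 1-D: new = best - r*|rand*best - current|*cos(theta)
  set.seed(9); u3 <- runif(1)
  set.seed(9)
  expect_equal(scso_exploit(1, 2, 1, 0), 2 - abs(u3 * 2 - 1))
  expect_equal(scso_exploit(1, 2, 0, 0), 2)        # r = 0 -> best exactly
  expect_equal(scso_exploit(1, 2, 1, 90), 2)       # cos(90 deg) = 0 -> best
  expect_error(scso_explore(1:2, 1:3, 1), "dimension mismatch")
})

test_that("roulette-wheel angle is an integer degree with uniform marginal", {
  set.seed(4)
  a <- replicate(1e4, scso_angle())
  expect_true(all(a >= 0 & a <= 360))
  expect_true(all(a == floor(a)))
  expect_lt(abs(mean(a) - 180), 5)
  set.seed(11); s1 <- replicate(50, scso_angle())
  set.seed(11); s2 <- replicate(50, scso_angle())
  expect_identical(s1, s2)
})

test_that("the swarm finds the optimum of a separable quadratic bowl", {
  centre <- c(2, -3, 0.5, 7, -1)
  fn <- function(x) -sum((x - centre)^2)
  dist <- sapply(1:10, function(sd) {
    res <- scso_optimize(fn, rep(-10, 5), rep(10, 5),
                         scso_control(pop_size = 50, max_iter = 100, seed = sd))
    expect_false(is.unsorted(res$history))       # elitist history
    sqrt(sum((res$par - centre)^2))
  })
  # the attack phase refines at rate r * |rand * best - current|, so most
  # but not all runs land inside 0.5 of the optimum; all must come close
  expect_gte(sum(dist < 0.5), 7)
  expect_lt(median(dist), 0.2)
  expect_lt(max(dist), 2)
})

test_that("agents respect bounds, runs are reproducible, degenerate cases work", {
  seen <- new.env(); seen$bad <- 0L
  lo <- c(-1, 0); hi <- c(1, 2)
  fn <- function(x) {
    if (any(x < lo - 1e-12) || any(x > hi + 1e-12)) seen$bad <- seen$bad + 1L
    sum(x)
  }
  r1 <- scso_optimize(fn, lo, hi, scso_control(15, 20, seed = 5))
  expect_identical(seen$bad, 0L)
  r2 <- scso_optimize(fn, lo, hi, scso_control(15, 20, seed = 5))
  expect_identical(r1, r2)                       # bit-for-bit given the seed

  flat <- scso_optimize(function(x) 1, 0, 1, scso_control(5, 10, seed = 1))
  expect_equal(flat$history, rep(1, 10))

  vals <- new.env(); vals$v <- numeric(0)
  two <- scso_optimize(function(x) {
    v <- if (x[1] < 0.5) 0.1 else 0.9
    vals$v <- c(vals$v, v)
    v
  }, 0, 1, scso_control(2, 1, seed = 2))
  expect_equal(two$value, max(vals$v))   # best of the evaluated set
  expect_error(scso_optimize(function(x) stop("boom"), 0, 1,
                             scso_control(5, 2, seed = 1)),
               "fitness function failed")
})

test_that("SCSO beats random search on a quadratic bowl at equal budget", {
  centre <- c(2, -3, 0.5, 7, -1)
  fn <- function(x) -sum((x - centre)^2)
  n_seeds <- 6
  budget <- 20 * (30 + 1)
  scso_best <- sapply(1:n_seeds, function(sd) {
    scso_optimize(fn, rep(-10, 5), rep(10, 5),
                  scso_control(20, 30, seed = sd))$value
  })
  rand_best <- sapply(1:n_seeds, function(sd) {
    set.seed(sd)
    max(replicate(budget, fn(runif(5, -10, 10))))
  })
  expect_gt(median(scso_best), median(rand_best))
})

test_that("target-fitness early stop preserves the recorded optimum", {
  fn <- function(x) min(1, 1 - abs(x[1] - 0.3))
  full <- scso_optimize(fn, 0, 1, scso_control(10, 30, seed = 3))
  stopped <- scso_optimize(fn, 0, 1,
                           scso_control(10, 30, seed = 3,
                                        target_fitness = full$value))
  expect_equal(stopped$value, full$value)
  expect_lte(stopped$evaluations, full$evaluations)
  expect_equal(stopped$history[length(stopped$history)],
               full$history[length(full$history)])
})
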