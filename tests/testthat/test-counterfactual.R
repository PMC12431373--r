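test_that("objective components behave at the degenerate corners", {
  set.seed(81)
  training <- matrix(rnorm(100 * 3, sd = 2), 100, 3)
  model <- function(X) as.numeric(X[, 1] > 0)   # already-certain classifier
  x <- c(4, 0, 0)                               # model says class 1 at x
  q <- cf_query(x, target_class = 1, k = 1, actionable = 0L,
                ranges = matrix(c(-10, 10), 2, 1))
  obj <- cf_objective(matrix(x, 1), q, model, scale = rep(1, 3))
  expect_equal(obj$mean_yloss, 0)
  expect_equal(obj$mean_dist, 0)

  # duplicate candidates: singular kernel floored, objective stays finite
  q2 <- cf_query(x, 1, k = 2, actionable = 0L,
                 ranges = matrix(c(-10, 10), 2, 1))
  dup <- rbind(x, x)
  obj2 <- cf_objective(dup, q2, model, scale = rep(1, 3))
  expect_equal(obj2$diversity, log(1e-12))
  expect_true(is.finite(obj2$total))
})

test_that("the DPP term strictly prefers diverse candidate pairs", {
  model <- function(X) rep(1, nrow(X))          # losses identical everywhere
  x <- c(0, 0)
  q <- cf_query(x, 1, k = 2, actionable = 0:1,
                ranges = matrix(c(-10, -10, 10, 10), 2, 2, byrow = TRUE),
                lambda1 = 0)                    # isolate the diversity term
  far <- rbind(c(5, 5), c(-5, -5))
  near <- rbind(c(5, 5), c(5, 5.01))
  scale <- rep(1, 2)
  expect_lt(cf_objective(far, q, model, scale)$total,
            cf_objective(near, q, model, scale)$total)

  # permutation invariance in the candidate order
  expect_equal(cf_objective(far, q, model, scale)$diversity,
               cf_objective(far[2:1, ], q, model, scale)$diversity)
})

test_that("threshold-model search yields valid, actionable-only counterfactuals", {
  set.seed(91)
  training <- cbind(runif(200, 0, 10), rnorm(200), rnorm(200))
  model <- threshold_model(col = 1L, cut = 5)
  x <- c(3, 1.5, -0.4)                          # class 0; want class 1
  q <- cf_query(x, target_class = 1, k = 4, actionable = 0L,
                ranges = matrix(c(0, 10), 2, 1))
  cf <- generate_counterfactuals(model, q, training,
                                 scso_control(20, 25, seed = 91))
  expect_s3_class(cf, "gs_counterfactuals")
  expect_gte(sum(cf$valid), 1)
  # every valid candidate crossed the threshold ...
  expect_true(all(cf$candidates[cf$valid, 1] > 5))
  # ... and no candidate touched a non-actionable coordinate
  expect_true(all(cf$candidates[, 2] == x[2]))
  expect_true(all(cf$candidates[, 3] == x[3]))
  # candidates stay inside the declared ranges
  expect_true(all(cf$candidates[, 1] >= 0 & cf$candidates[, 1] <= 10))

  # same seed, same result
  cf2 <- generate_counterfactuals(model, q, training,
                                  scso_control(20, 25, seed = 91))
  expect_identical(cf$candidates, cf2$candidates)
})

test_that("a target equal to the current class admits a zero-distance solution", {
  training <- matrix(runif(300, 0, 10), 100, 3)
  model <- threshold_model(col = 1L, cut = 5)
  x <- c(8, 2, 2)                               # already class 1
  q <- cf_query(x, target_class = 1, k = 2, actionable = 0L,
                ranges = matrix(c(0, 10), 2, 1))
  # x itself scores zero loss and zero distance under the objective
  obj <- cf_objective(rbind(x, x), q, model, mad_scale_for_test(training))
  expect_equal(obj$mean_yloss, 0)
  expect_equal(obj$mean_dist, 0)
  cf <- generate_counterfactuals(model, q, training,
                                 scso_control(15, 15, seed = 5))
  expect_true(all(cf$predicted_class[cf$valid] == 1))
})

test_that("counterfactual tables render original -> changed values", {
  model <- threshold_model(col = 1L, cut = 5)
  training <- matrix(runif(300, 0, 10), 100, 3)
  sch <- data.frame(index = 0:2, name = c("A", "B", "C"), kind = "continuous",
                    description = "")
  q <- cf_query(c(3, 1, 1), 1, k = 2, actionable = 0L,
                ranges = matrix(c(0, 10), 2, 1))
  cf <- generate_counterfactuals(model, q, training,
                                 scso_control(15, 15, seed = 2))
  tab <- cf_table(cf, sch)
  expect_equal(nrow(tab), 2)
  expect_true(all(grepl("->", tab$A[tab$valid])))
  expect_named(tab, c("serial", "A", "predicted_class", "valid"))
})
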