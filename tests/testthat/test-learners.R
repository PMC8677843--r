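# Small shared regression problem: linear signal + noise.
make_xy <- function(n = 120, seed = 1) {
  withr::with_seed(seed, {
    x <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    list(x = x, y = 2 + 1.5 * x[, "a"] - x[, "b"] + rnorm(n, 0, 0.3))
  })
}

test_that("grid search honours budgets, grids of one, and the tenfold default", {
  d <- make_xy()
  spec1 <- learner_spec("glm", grid = list(alpha = 0, lambda = 0.01))
  out <- random_grid_search(spec1, d$x, d$y, folds = 4, seed = 1)
  expect_length(out, 1)
  expect_equal(out[[1]]$params$alpha, 0)

  spec2 <- learner_spec("glm", grid = list(alpha = c(0, 0.5, 1),
                                           lambda = c(0.01, 0.1)),
                        budget = 3)
  out2 <- random_grid_search(spec2, d$x, d$y, folds = 4, seed = 2)
  expect_length(out2, 3)
  cv <- vapply(out2, `[[`, 0, "cv_rmse")
  expect_equal(cv, sort(cv))  # ordered by CV RMSE

  # tenfold cross-validation is the default K
  expect_equal(formals(random_grid_search)$folds, 10)
  expect_equal(formals(stack_ensemble)$folds, 10)
})

test_that("tree learners record the early-stopping card and truncate stagnation", {
  # the truncation rule itself: improvement < tol for 2 consecutive events
  # two consecutive sub-tolerance improvements confirm stagnation; the
  # kept model is the last iteration before the stagnant run
  err <- c(10, 8, 6, 5.999, 5.9985, 5.998, 5.9)
  expect_equal(geostackx:::stop_iteration(err, 0.001, 2), 3)
  expect_equal(geostackx:::stop_iteration(c(5, 4, 3, 2), 0.001, 2), 4)

  d <- make_xy()
  spec <- learner_spec("xgboost", grid = list(nrounds = 60, eta = 0.3,
                                              max_depth = 3))
  out <- random_grid_search(spec, d$x, d$y, folds = 3, seed = 3)
  card <- out[[1]]$card
  expect_equal(card$early_stop$tolerance, 0.001)
  expect_equal(card$early_stop$rounds, 2)
  expect_lte(out[[1]]$params$nrounds, 60)
})

test_that("out-of-fold predictions are honest and permutation-equivariant", {
  d <- make_xy(80, seed = 4)
  spec <- learner_spec("glm", grid = list(alpha = 0, lambda = 0.01))
  learners <- random_grid_search(spec, d$x, d$y, folds = 4, seed = 5)
  folds <- make_folds(80, 4, seed = 6)
  M <- oof_predictions(learners, d$x, d$y, fold_ids = folds, seed = 7)
  expect_equal(dim(M), c(80, 1))
  expect_false(anyNA(M))

  # leakage: corrupting the response of rows in fold 1 must leave the
  # out-of-fold predictions of fold 1 unchanged (their models never saw it)
  y2 <- d$y
  y2[folds == 1] <- y2[folds == 1] + 100
  M2 <- oof_predictions(learners, d$x, y2, fold_ids = folds, seed = 7)
  expect_equal(M[folds == 1, 1], M2[folds == 1, 1], tolerance = 1e-10)
  expect_gt(max(abs(M[folds != 1, 1] - M2[folds != 1, 1])), 1)

  # permutation equivariance: shuffling rows then unshuffling is a no-op
  perm <- withr::with_seed(8, sample.int(80))
  Mp <- oof_predictions(learners, d$x[perm, ], d$y[perm],
                        fold_ids = folds[perm], seed = 7)
  expect_equal(Mp[order(perm), 1], M[, 1], tolerance = 1e-10)
})

test_that("a perfect learner gives meta-features equal to the response, and LOO runs", {
  d <- make_xy(20, seed = 9)
  truth <- 2 + 1.5 * d$x[, "a"] - d$x[, "b"]
  oracle_learner <- structure(
    list(family = "glm", params = list(), cv_rmse = 0,
         fit = structure(list(family = "oracle"), class = "oracle_fit")),
    class = "tuned_learner")
  # an oracle that reconstructs the noiseless response from the features
  assign("predict.oracle_fit",
         function(object, newx, ...) 2 + 1.5 * newx[, "a"] - newx[, "b"],
         envir = globalenv())
  on.exit(rm("predict.oracle_fit", envir = globalenv()), add = TRUE)
  with_mocked_bindings(
    fit_base_learner = function(family, params, x, y, ...)
      structure(list(family = "oracle"), class = "oracle_fit"),
    {
      M <- oof_predictions(list(oracle_learner), d$x, truth,
                           fold_ids = make_folds(20, 20, seed = 1))
      expect_equal(M[, 1], truth, tolerance = 1e-12)
    }
  )
})

test_that("the stack recovers a single truthful base learner with weight one", {
  set.seed(10)
  n <- 1000
  x <- cbind(a = rnorm(n), b = rnorm(n))
  y <- 1 + 2 * x[, "a"] + rnorm(n, 0, 0.4)
  spec <- learner_spec("glm", grid = list(alpha = 0, lambda = 1e-4))
  learners <- random_grid_search(spec, x, y, folds = 5, seed = 11)
  folds <- make_folds(n, 5, seed = 11)
  M <- oof_predictions(learners, x, y, fold_ids = folds, seed = 11)
  sm <- fit_stack(M, y, learners)
  expect_lt(abs(sm$meta_coefs[1] - 1), 0.05)
  expect_lt(abs(sm$meta_intercept), 0.05 * sd(y))
})

test_that("stack predictions are exactly the meta-linear combination", {
  d <- make_xy(100, seed = 12)
  fit <- stack_ensemble(y ~ a + b + c,
                        data = data.frame(d$x, y = d$y),
                        families = c("glm", "rf"), folds = 3, budget = 2,
                        seed = 13)
  newdata <- data.frame(a = rnorm(10), b = rnorm(10), c = rnorm(10))
  x <- geostackx:::build_design(stats::delete.response(fit$terms),
                                newdata, fit$xlevels)$x
  base_preds <- vapply(fit$stack$learners,
                       function(l) predict(l$fit, x), numeric(10))
  manual <- fit$stack$meta_intercept +
    as.numeric(base_preds %*% fit$stack$meta_coefs)
  expect_equal(predict(fit, newdata), manual, tolerance = 1e-12)

  # best-of-family keeps one candidate per family
  bof <- fit_stack(fit$meta, fit$y, fit$candidates, mode = "best_of_family")
  expect_equal(sort(unique(vapply(bof$learners, `[[`, "", "family"))),
               sort(unique(fit$cv$family)))
  expect_length(bof$learners, length(unique(fit$cv$family)))
})

test_that("collinear meta-features never break the ridge meta-learner", {
  d <- make_xy(60, seed = 14)
  spec <- learner_spec("glm", grid = list(alpha = 0,
                                          lambda = c(1e-4, 1.0001e-4)))
  learners <- random_grid_search(spec, d$x, d$y, folds = 3, seed = 15)
  folds <- make_folds(60, 3, seed = 15)
  M <- oof_predictions(learners, d$x, d$y, fold_ids = folds, seed = 15)
  expect_gt(cor(M[, 1], M[, 2]), 0.999)  # near-duplicate columns
  sm <- fit_stack(M, d$y, learners)
  expect_true(all(is.finite(sm$meta_coefs)))
})

test_that("model object methods behave", {
  tab <- small_counties(10, 10, seed = 16)
  fit <- stack_ensemble(response ~ smoking + elevation + poverty, data = tab,
                        families = c("glm", "xgboost"), folds = 3,
                        budget = 1, seed = 17)
  expect_s3_class(fit, "stack_ensemble")
  expect_output(print(fit), "Stacked ensemble")
  expect_output(print(summary(fit)), "Meta-learner coefficients")
  expect_length(coef(fit), length(fit$stack$learners) + 1)
  expect_equal(fitted(fit) + residuals(fit), fit$y)
  expect_equal(length(predict(fit, tab)), nrow(tab))
})
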