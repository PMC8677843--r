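`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- learner specifications -------------------------------------------------

canonical_family <- function(family) {
  map <- c("penalized-linear" = "glm", glm = "glm",
           "random-forest" = "rf", rf = "rf",
           "gradient-boosting" = "gbm", gbm = "gbm",
           "extreme-gradient-boosting" = "xgboost", xgboost = "xgboost",
           "multilayer-perceptron" = "mlp", mlp = "mlp", dnn = "mlp")
  out <- unname(map[family])
  if (anyNA(out)) stop("unknown learner family: ",
                       paste(family[is.na(out)], collapse = ", "))
  out
}

#' Base-learner specification
#'
#' Declares one family of base learners and its hyperparameter grid for
#' random grid search. Default grids are seeded with the hyperparameter
#' values reported as optima in large county-mortality stacking studies
#' (e.g. 576 trees / depth 30 / sample rate 0.6 for the random forest;
#' 500 rounds / column sample 0.5 / depth 20 for gradient boosting;
#' 350 rounds / depth 3 / minimum child weight 50 / column sample 0.75
#' for extreme gradient boosting; elastic-net alpha 0 / lambda 1) but
#' are ordinary tunables, not asserted optima. Tree families honour
#' early stopping with a relative RMSE "stopping tolerance" and a number
#' of consecutive "stopping rounds" (defaults 0.001 and 2).
#'
#' @param family One of `penalized-linear`/`glm`, `random-forest`/`rf`,
#'   `gradient-boosting`/`gbm`, `extreme-gradient-boosting`/`xgboost`,
#'   `multilayer-perceptron`/`mlp`.
#' @param grid Named list of candidate hyperparameter values
#'   (`NULL` = the family default grid).
#' @param budget Maximum number of grid combinations to evaluate.
#' @param early_stop Named vector `c(tolerance=, rounds=)` for tree
#'   families.
#' @return A `learner_spec` object.
#' @export
learner_spec <- function(family, grid = NULL, budget = 20,
                         early_stop = c(tolerance = 0.001, rounds = 2)) {
  family <- canonical_family(family)
  if (is.null(grid)) grid <- default_grid(family)
  if (!length(grid)) stop("grid must be nonempty")
  if (budget < 1) stop("budget must be >= 1")
  structure(list(family = family, grid = grid, budget = budget,
                 early_stop = early_stop),
            class = "learner_spec")
}

default_grid <- function(family) {
  switch(family,
    glm = list(alpha = c(0, 0.5, 1), lambda = c(0.01, 0.1, 1)),
    rf = list(num.trees = c(250, 576), max.depth = c(0, 30),
              sample.fraction = c(0.6, 1), mtry_frac = c(1 / 3, 0.6)),
    gbm = list(nrounds = 500, eta = c(0.05, 0.1), max_depth = c(5, 20),
               min_child_weight = c(1, 10), colsample_bytree = c(0.5, 1)),
    xgboost = list(nrounds = 350, eta = c(0.1, 0.3), max_depth = c(3, 6),
                   min_child_weight = c(10, 50),
                   colsample_bytree = c(0.75, 1)),
    mlp = list(size = c(5, 10, 20), decay = c(1e-4, 1e-2), maxit = 300),
    stop("unknown family: ", family)
  )
}

#' Default panel of learner specifications
#'
#' @param families Families to include (default: all five).
#' @param budget Grid-search budget per family.
#' @return Named list of [learner_spec()] objects.
#' @export
default_learner_specs <- function(families = c("glm", "rf", "gbm",
                                               "xgboost", "mlp"),
                                  budget = 4) {
  fams <- canonical_family(families)
  stats::setNames(lapply(fams, learner_spec, budget = budget), fams)
}

# ---- single-model fitting ---------------------------------------------------

# glmnet refuses single-column x; pad with a zero column when needed.
pad_x <- function(x) {
  if (ncol(x) >= 2) return(x)
  cbind(x, `.pad` = 0)
}

# Truncation point of a boosting trajectory under the early-stop rule:
# stop once the relative RMSE improvement has been below `tolerance`
# for `rounds` consecutive scoring events.
stop_iteration <- function(errors, tolerance = 0.001, rounds = 2) {
  m <- length(errors)
  if (m <= rounds) return(m)
  rel <- (errors[-m] - errors[-1]) / pmax(errors[-m], .Machine$double.eps)
  run <- 0
  for (t in seq_along(rel)) {
    run <- if (rel[t] < tolerance) run + 1 else 0
    if (run == rounds) return(t + 1 - rounds)
  }
  m
}

fit_base_learner <- function(family, params, x, y, seed = 0,
                             valid = NULL, early_stop = NULL) {
  obj <- list(family = family, params = params)
  if (family == "glm") {
    obj$fit <- glmnet::glmnet(pad_x(x), y, alpha = params$alpha %||% 0,
                              lambda = params$lambda %||% 1)
  } else if (family == "rf") {
    md <- params$max.depth %||% 0
    obj$fit <- ranger::ranger(
      x = x, y = y,
      num.trees = params$num.trees %||% 500,
      max.depth = if (md == 0) NULL else md,
      sample.fraction = params$sample.fraction %||% 1,
      replace = FALSE,
      mtry = max(1L, floor((params$mtry_frac %||% (1 / 3)) * ncol(x))),
      seed = seed, num.threads = 1)
  } else if (family %in% c("gbm", "xgboost")) {
    xp <- list(objective = "reg:squarederror",
               eta = params$eta %||% 0.1,
               max_depth = params$max_depth %||% 6,
               min_child_weight = params$min_child_weight %||% 1,
               subsample = params$subsample %||% 1,
               colsample_bytree = params$colsample_bytree %||% 1,
               nthread = 1, seed = seed)
    dtrain <- xgboost::xgb.DMatrix(x, label = y)
    nrounds <- params$nrounds %||% 200
    if (!is.null(valid)) {
      dval <- xgboost::xgb.DMatrix(valid$x, label = valid$y)
      fit <- xgboost::xgb.train(params = xp, data = dtrain, nrounds = nrounds,
                                evals = list(valid = dval), verbose = 0)
      log <- attributes(fit)$evaluation_log
      es <- early_stop %||% c(tolerance = 0.001, rounds = 2)
      obj$best_iter <- stop_iteration(log$valid_rmse,
                                      tolerance = es[["tolerance"]],
                                      rounds = es[["rounds"]])
      obj$fit <- fit
    } else {
      obj$fit <- xgboost::xgb.train(params = xp, data = dtrain,
                                    nrounds = nrounds, verbose = 0)
    }
  } else if (family == "mlp") {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0] <- 1
    xs <- scale(x, center = ctr, scale = scl)
    obj$center <- ctr; obj$scale <- scl
    obj$y_center <- mean(y); obj$y_scale <- max(stats::sd(y), 1e-8)
    set.seed(seed)
    obj$fit <- nnet::nnet(xs, (y - obj$y_center) / obj$y_scale,
                          size = params$size %||% 10,
                          decay = params$decay %||% 1e-4,
                          maxit = params$maxit %||% 300,
                          linout = TRUE, trace = FALSE, MaxNWts = 25000)
  } else stop("unknown family: ", family)
  class(obj) <- "base_learner"
  obj
}

#' @export
predict.base_learner <- function(object, newx, ...) {
  switch(object$family,
    glm = as.numeric(stats::predict(object$fit, newx = pad_x(newx))),
    rf = stats::predict(object$fit, data = newx, num.threads = 1)$predictions,
    gbm = ,
    xgboost = {
      if (!is.null(object$best_iter))
        stats::predict(object$fit, newx,
                       iterationrange = c(1, object$best_iter))
      else stats::predict(object$fit, newx)
    },
    mlp = {
      xs <- scale(newx, center = object$center, scale = object$scale)
      as.numeric(stats::predict(object$fit, xs)) * object$y_scale +
        object$y_center
    },
    stop("unknown family"))
}

# ---- cross-validation machinery ---------------------------------------------

#' Cross-validation fold assignment
#'
#' Balanced fold labels (sizes differing by at most one), seeded so the
#' same assignment can be shared across all learners.
#'
#' @param n Number of rows.
#' @param folds Number of folds K (2 <= K <= n).
#' @param seed Optional integer seed.
#' @return Integer vector of fold labels in `1:folds`.
#' @export
make_folds <- function(n, folds = 10, seed = NULL) {
  if (folds < 2 || folds > n) stop("folds must be in [2, n]")
  draw <- function() sample(rep_len(seq_len(folds), n))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Random grid search with K-fold cross-validation
#'
#' Samples up to `spec$budget` hyperparameter combinations without
#' replacement from `spec$grid` (the full grid when the budget
#' covers it), scores each by K-fold cross-validated RMSE under a shared
#' fold assignment, and refits every candidate on the full data. Tree
#' families use the held fold of each split as an early-stopping monitor
#' (relative-improvement rule, see [learner_spec()]); the full-data
#' refit uses the median stopped round across folds.
#'
#' @param spec A [learner_spec()].
#' @param x Numeric design matrix (rows = training units).
#' @param y Numeric response.
#' @param folds Number of CV folds (default 10).
#' @param seed Optional integer seed (grid sampling and model seeds).
#' @param fold_ids Optional externally shared fold assignment.
#' @return List of `tuned_learner` objects ordered by `cv_rmse`.
#' @export
random_grid_search <- function(spec, x, y, folds = 10, seed = NULL,
                               fold_ids = NULL) {
  stopifnot(inherits(spec, "learner_spec"))
  grid <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  n_comb <- nrow(grid)
  take <- min(spec$budget, n_comb)
  pick <- if (is.null(seed)) sample.int(n_comb, take)
          else withr::with_seed(derive_seed(seed, 11), sample.int(n_comb, take))
  if (is.null(fold_ids)) fold_ids <- make_folds(nrow(x), folds, seed)
  K <- max(fold_ids)
  tree <- spec$family %in% c("gbm", "xgboost")

  out <- lapply(seq_along(pick), function(ci) {
    params <- as.list(grid[pick[ci], , drop = FALSE])
    preds <- rep(NA_real_, nrow(x))
    iters <- integer(0)
    for (k in seq_len(K)) {
      tr <- fold_ids != k
      if (sum(tr) < 2) stop("training part of fold ", k, " has < 2 rows")
      fseed <- derive_seed(seed %||% 0, 100 + 37 * ci + k)
      fit <- fit_base_learner(
        spec$family, params, x[tr, , drop = FALSE], y[tr], seed = fseed,
        valid = if (tree) list(x = x[!tr, , drop = FALSE], y = y[!tr]),
        early_stop = spec$early_stop)
      preds[!tr] <- predict(fit, x[!tr, , drop = FALSE])
      if (tree) iters <- c(iters, fit$best_iter)
    }
    cv_rmse <- sqrt(mean((y - preds)^2))
    chosen <- params
    if (tree) chosen$nrounds <- max(1L, as.integer(round(stats::median(iters))))
    full <- fit_base_learner(spec$family, chosen, x, y,
                             seed = derive_seed(seed %||% 0, 100 + 37 * ci))
    structure(list(family = spec$family, params = chosen, cv_rmse = cv_rmse,
                   fit = full,
                   card = list(family = spec$family,
                               hyperparameters = chosen,
                               cv_rmse = cv_rmse,
                               early_stop = as.list(spec$early_stop))),
              class = "tuned_learner")
  })
  out[order(vapply(out, `[[`, 0, "cv_rmse"))]
}

#' Out-of-fold meta-features
#'
#' For every tuned learner, refits its chosen hyperparameters on each
#' K-1 fold complement and predicts the held fold, producing an
#' `n x n_learners` matrix in which entry (i, l) was produced by a model
#' never trained on row i (the stacking "honesty" invariant).
#'
#' @param learners List of `tuned_learner` objects.
#' @param x,y Training design matrix and response.
#' @param fold_ids Shared fold assignment (required so meta-features are
#'   comparable across learners); built from `folds`/`seed` if omitted.
#' @param folds,seed Used only when `fold_ids` is missing.
#' @return A `meta_features` matrix with attributes `fold_ids` and
#'   `labels`.
#' @export
oof_predictions <- function(learners, x, y, fold_ids = NULL, folds = 10,
                            seed = NULL) {
  if (is.null(fold_ids)) fold_ids <- make_folds(nrow(x), folds, seed)
  K <- max(fold_ids)
  M <- matrix(NA_real_, nrow(x), length(learners))
  for (l in seq_along(learners)) {
    ln <- learners[[l]]
    tree <- ln$family %in% c("gbm", "xgboost")
    for (k in seq_len(K)) {
      tr <- fold_ids != k
      if (sum(tr) < 2) stop("training part of fold ", k, " has < 2 rows")
      fit <- fit_base_learner(ln$family, ln$params, x[tr, , drop = FALSE],
                              y[tr], seed = derive_seed(seed %||% 0,
                                                        500 + 13 * l + k))
      M[!tr, l] <- predict(fit, x[!tr, , drop = FALSE])
    }
  }
  labels <- vapply(seq_along(learners), function(l)
    paste0(learners[[l]]$family, "_", l), "")
  structure(M, fold_ids = fold_ids, labels = labels,
            class = c("meta_features", class(M)))
}

#' Fit the stacked ensemble meta-learner
#'
#' Ridge-regularized least squares of the response on the out-of-fold
#' meta-features (intercept unpenalized); the small default penalty
#' exists only to absorb collinearity among base-learner predictions,
#' which is otherwise common in stacks. `mode = "best_of_family"`
#' restricts the stack to the lowest-CV-RMSE candidate of each family;
#' `mode = "all_models"` uses every candidate.
#'
#' @param meta A `meta_features` matrix from [oof_predictions()].
#' @param y Training response.
#' @param learners The tuned learners matching the columns of `meta`
#'   (already refit on the full training data).
#' @param mode `"all_models"` or `"best_of_family"`.
#' @param ridge_penalty Nonnegative ridge penalty (default 1e-6).
#' @param nonnegative Constrain meta coefficients to be nonnegative
#'   (solved via a ridge fit with lower limits).
#' @return A `stack_model`: selected learners, meta intercept and
#'   coefficients. Predictions are
#'   `intercept + sum(coef_l * base_l(x))`.
#' @export
fit_stack <- function(meta, y, learners,
                      mode = c("all_models", "best_of_family"),
                      ridge_penalty = 1e-6, nonnegative = FALSE) {
  mode <- match.arg(mode)
  stopifnot(ncol(meta) == length(learners))
  sel <- seq_along(learners)
  if (mode == "best_of_family") {
    fams <- vapply(learners, `[[`, "", "family")
    cvs <- vapply(learners, `[[`, 0, "cv_rmse")
    sel <- vapply(unique(fams), function(f) {
      idx <- which(fams == f); idx[which.min(cvs[idx])]
    }, 0L)
    sel <- sort(unname(sel))
  }
  Z <- unclass(meta)[, sel, drop = FALSE]
  labels <- attr(meta, "labels")[sel]
  if (nonnegative) {
    fit <- glmnet::glmnet(pad_x(Z), y, alpha = 0,
                          lambda = ridge_penalty / length(y),
                          lower.limits = 0)
    beta <- as.numeric(fit$beta)[seq_len(ncol(Z))]
    intercept <- as.numeric(fit$a0)
  } else {
    zc <- colMeans(Z); yc <- mean(y)
    Zc <- sweep(Z, 2, zc)
    A <- crossprod(Zc) + diag(ridge_penalty, ncol(Z))
    beta <- as.numeric(solve(A, crossprod(Zc, y - yc)))
    intercept <- yc - sum(zc * beta)
  }
  structure(list(learners = learners[sel], labels = labels,
                 meta_intercept = intercept, meta_coefs = beta,
                 mode = mode, ridge_penalty = ridge_penalty,
                 nonnegative = nonnegative),
            class = "stack_model")
}

#' @export
predict.stack_model <- function(object, newx, ...) {
  P <- vapply(object$learners, function(l) predict(l$fit, newx),
              numeric(nrow(newx)))
  if (nrow(newx) == 1) P <- matrix(P, nrow = 1)
  as.numeric(object$meta_intercept + P %*% object$meta_coefs)
}

# ---- the user-facing fitting function ---------------------------------------

build_design <- function(terms, data, xlevels = NULL) {
  mf <- stats::model.frame(terms, data, xlev = xlevels, na.action = stats::na.fail)
  x <- stats::model.matrix(terms, mf)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  list(x = x, y = if (attr(terms, "response")) stats::model.response(mf),
       mf = mf)
}

#' Stacked-ensemble regression
#'
#' Fits the full stacked-generalization pipeline to a training table:
#' every requested base-learner family is tuned by random grid search
#' under shared K-fold cross-validation ([random_grid_search()]), all
#' candidates produce honest out-of-fold meta-features
#' ([oof_predictions()]), and a ridge meta-learner combines them
#' ([fit_stack()]). Returns a classed model object with the usual
#' `predict`/`print`/`summary`/`coef`/`residuals`/`fitted` methods.
#'
#' @param formula Model formula, e.g. `response ~ smoking + poverty + ...`.
#' @param data Training data frame (factors allowed; they are expanded
#'   to treatment contrasts).
#' @param specs Named list of [learner_spec()] objects
#'   (default: [default_learner_specs()] over `families`).
#' @param families Families used when `specs` is `NULL`.
#' @param folds K for all cross-validation (default 10).
#' @param budget Grid budget per family when `specs` is `NULL`.
#' @param mode `"all_models"` (every tuned candidate enters the stack)
#'   or `"best_of_family"`.
#' @param ridge_penalty,nonnegative Meta-learner settings, see
#'   [fit_stack()].
#' @param seed Integer seed controlling folds, grid sampling and model
#'   seeds.
#' @return A `stack_ensemble` object.
#' @examples
#' \donttest{
#' tab <- simulate_counties(12, 12, seed = 1)
#' fit <- stack_ensemble(response ~ smoking + poverty + elevation,
#'                       data = tab, families = c("glm", "rf"),
#'                       folds = 3, budget = 2, seed = 1)
#' print(fit)
#' }
#' @export
stack_ensemble <- function(formula, data, specs = NULL,
                           families = c("glm", "rf", "gbm", "xgboost", "mlp"),
                           folds = 10, budget = 4,
                           mode = c("all_models", "best_of_family"),
                           ridge_penalty = 1e-6, nonnegative = FALSE,
                           seed = NULL) {
  mode <- match.arg(mode)
  trm <- stats::terms(formula, data = data)
  des <- build_design(trm, data)
  xlevels <- stats::.getXlevels(trm, des$mf)
  x <- des$x; y <- des$y
  if (is.null(specs)) specs <- default_learner_specs(families, budget)

  fold_ids <- make_folds(nrow(x), folds, seed)
  candidates <- list()
  for (i in seq_along(specs)) {
    cand <- random_grid_search(specs[[i]], x, y, fold_ids = fold_ids,
                               seed = derive_seed(seed %||% 0, 1000 + i))
    candidates <- c(candidates, cand)
  }
  meta <- oof_predictions(candidates, x, y, fold_ids = fold_ids, seed = seed)
  stack <- fit_stack(meta, y, candidates, mode = mode,
                     ridge_penalty = ridge_penalty, nonnegative = nonnegative)
  cv <- data.frame(
    label = attr(meta, "labels"),
    family = vapply(candidates, `[[`, "", "family"),
    cv_rmse = vapply(candidates, `[[`, 0, "cv_rmse"),
    stringsAsFactors = FALSE)
  obj <- structure(list(terms = trm, xlevels = xlevels,
                        candidates = candidates, stack = stack,
                        cv = cv, fold_ids = fold_ids, meta = meta,
                        y = y, fitted_values = predict(stack, x),
                        call = match.call()),
                   class = "stack_ensemble")
  obj
}

#' @export
predict.stack_ensemble <- function(object, newdata, ...) {
  trm <- stats::delete.response(object$terms)
  x <- build_design(trm, newdata, object$xlevels)$x
  predict(object$stack, x)
}

#' @export
print.stack_ensemble <- function(x, ...) {
  cat("Stacked ensemble (", x$stack$mode, "): ",
      length(x$stack$learners), " base learners of ",
      length(unique(x$cv$family)), " families, ridge meta-learner\n",
      sep = "")
  cat("Training rows:", length(x$y),
      " folds:", max(x$fold_ids), "\n")
  cat("Best CV RMSE by family:\n")
  best <- stats::aggregate(cv_rmse ~ family, x$cv, min)
  print(best, row.names = FALSE)
  invisible(x)
}

#' @export
summary.stack_ensemble <- function(object, ...) {
  co <- coef(object)
  res <- stats::residuals(object)
  out <- list(cv = object$cv, meta = co,
              train_rmse = sqrt(mean(res^2)),
              train_mae = mean(abs(res)),
              mode = object$stack$mode)
  class(out) <- "summary.stack_ensemble"
  out
}

#' @export
print.summary.stack_ensemble <- function(x, ...) {
  cat("Stacked ensemble (", x$mode, ")\n", sep = "")
  cat(sprintf("Training RMSE %.3f, MAE %.3f\n", x$train_rmse, x$train_mae))
  cat("Meta-learner coefficients:\n")
  print(round(x$meta, 4))
  cat("Base-learner CV RMSE:\n")
  print(x$cv, row.names = FALSE)
  invisible(x)
}

#' @export
coef.stack_ensemble <- function(object, ...) {
  stats::setNames(c(object$stack$meta_intercept, object$stack$meta_coefs),
                  c("(Intercept)", object$stack$labels))
}

#' @export
fitted.stack_ensemble <- function(object, ...) object$fitted_values

#' @export
residuals.stack_ensemble <- function(object, ...)
  object$y - object$fitted_values
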