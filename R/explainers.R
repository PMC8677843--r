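# All explainers are model-agnostic: they only need a prediction rule.
# Accept either a fitted object with a predict(object, newdata) method
# or a bare function(newdata) -> numeric.
model_predictor <- function(model) {
  if (is.function(model)) return(function(nd) as.numeric(model(nd)))
  function(nd) as.numeric(stats::predict(model, nd))
}

#' Permutation feature importance
#'
#' Measures the increase in prediction error (drop-out loss) after a
#' feature's column is permuted, breaking its relationship with the
#' response while leaving its marginal distribution intact. Both the
#' ratio `permuted_loss / baseline_loss` (the factor by which the loss
#' is increased) and the difference are reported, averaged over
#' `n_repeats` independent permutations.
#'
#' @param model Fitted model or prediction function.
#' @param data Data frame containing the features and the response.
#' @param response Response column name.
#' @param features Features to score (default: all non-response columns).
#' @param loss `"rmse"` (default) or `"mae"`.
#' @param n_repeats Permutations per feature (>= 1).
#' @param seed Optional integer seed; same seed, same result.
#' @return A `feature_importance` data frame (one row per feature,
#'   ranked by mean permuted loss descending): `feature`,
#'   `baseline_loss`, `permuted_loss`, `sd_permuted_loss`,
#'   `dropout_ratio`, `dropout_difference`, `n_repeats`.
#' @export
permutation_importance <- function(model, data, response,
                                   features = NULL,
                                   loss = c("rmse", "mae"),
                                   n_repeats = 5, seed = NULL) {
  loss <- match.arg(loss)
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  stopifnot(response %in% names(data))
  if (is.null(features)) features <- setdiff(names(data), response)
  lf <- if (loss == "rmse") rmse else mae
  pred <- model_predictor(model)
  y <- data[[response]]
  baseline <- lf(y, pred(data))
  if (baseline == 0)
    warning("zero baseline loss (perfect model): dropout ratios undefined")

  run <- function() {
    res <- lapply(features, function(f) {
      losses <- vapply(seq_len(n_repeats), function(r) {
        d <- data
        d[[f]] <- d[[f]][sample.int(nrow(d))]
        lf(y, pred(d))
      }, 0)
      data.frame(feature = f, baseline_loss = baseline,
                 permuted_loss = mean(losses),
                 sd_permuted_loss = stats::sd(losses),
                 dropout_ratio = if (baseline > 0) mean(losses) / baseline
                                 else NA_real_,
                 dropout_difference = mean(losses) - baseline,
                 n_repeats = n_repeats, stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out <- out[order(-out$permuted_loss), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("feature_importance", "data.frame")
  out
}

profile_grid <- function(x, grid_size) {
  if (!is.numeric(x)) return(levels(factor(x)))
  if (length(unique(x)) < 2) stop("constant feature")
  sort(unique(stats::quantile(x, probs = seq(0, 1, length.out = grid_size),
                              names = FALSE, type = 7)))
}

# Mean prediction with `feature` substituted by each grid value;
# one batched predict call per profile.
marginal_means <- function(pred, data, feature, grid, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(data))
  blocks <- lapply(grid, function(g) {
    d <- data[rows, , drop = FALSE]
    d[[feature]] <- if (is.factor(data[[feature]]))
      factor(g, levels = levels(data[[feature]])) else g
    d
  })
  big <- do.call(rbind, blocks)
  p <- pred(big)
  vapply(seq_along(grid), function(k)
    mean(p[((k - 1) * length(rows) + 1):(k * length(rows))]), 0)
}

#' Partial-dependence profile
#'
#' The marginal average prediction as a function of one feature: at each
#' grid value g, every reference row has the feature set to g and the
#' predictions are averaged. The grid uses empirical quantiles
#' (default 51 points); categorical features are profiled per level.
#'
#' @param model Fitted model or prediction function.
#' @param data Reference data frame (feature columns).
#' @param feature Feature name.
#' @param grid_size Number of quantile grid points.
#' @return A `xai_profile` data frame: `feature`, `grid`, `yhat`, `kind`.
#' @export
pd_profile <- function(model, data, feature, grid_size = 51) {
  stopifnot(feature %in% names(data))
  pred <- model_predictor(model)
  grid <- profile_grid(data[[feature]], grid_size)
  yhat <- marginal_means(pred, data, feature, grid)
  new_profile(feature, grid, yhat, "PD")
}

new_profile <- function(feature, grid, yhat, kind, weights = NULL) {
  out <- data.frame(feature = feature, grid = grid, yhat = yhat,
                    kind = kind, stringsAsFactors = FALSE)
  if (!is.null(weights)) attr(out, "weights") <- weights
  class(out) <- c("xai_profile", "data.frame")
  out
}

#' Local-dependence profile
#'
#' Conditional version of the partial-dependence profile: at grid value
#' g only the rows whose feature value lies in the empirical
#' neighbourhood of g (the nearest `neighborhood_frac` fraction) are
#' averaged, with the feature set to g. With `neighborhood_frac = 1`
#' the conditioning is vacuous and LD equals PD; under dependent
#' features LD and PD diverge, which is the diagnostic use of the pair.
#'
#' @inheritParams pd_profile
#' @param neighborhood_frac Fraction of rows in each conditioning
#'   neighbourhood, in (0, 1].
#' @return A `xai_profile` data frame.
#' @export
ld_profile <- function(model, data, feature, grid_size = 51,
                       neighborhood_frac = 0.25) {
  stopifnot(feature %in% names(data))
  if (neighborhood_frac <= 0 || neighborhood_frac > 1)
    stop("neighborhood_frac must be in (0, 1]")
  if (!is.numeric(data[[feature]]))
    stop("local-dependence profiles require a numeric feature")
  pred <- model_predictor(model)
  x <- data[[feature]]
  grid <- profile_grid(x, grid_size)
  k <- max(1L, ceiling(neighborhood_frac * length(x)))
  yhat <- vapply(grid, function(g) {
    rows <- order(abs(x - g))[seq_len(k)]
    if (!length(rows)) stop("empty neighbourhood at grid value ", g)
    marginal_means(pred, data, feature, g, rows = rows)
  }, 0)
  new_profile(feature, grid, yhat, "LD")
}

#' Accumulated-local-effects profile
#'
#' Partitions the feature range into quantile intervals, averages the
#' model's finite differences across each interval over the rows that
#' fall in it (a local, extrapolation-free effect), accumulates the
#' interval effects, and mean-centres the result with the empirical
#' interval weights. Unbiased under correlated features, unlike partial
#' dependence.
#'
#' @inheritParams pd_profile
#' @param n_intervals Number of quantile intervals (>= 2); empty
#'   intervals are merged with a neighbour and noted via a message.
#' @return A `xai_profile` data frame over the interval edges, with the
#'   empirical edge weights in attribute `weights`
#'   (`sum(weights * yhat) == 0`).
#' @export
al_profile <- function(model, data, feature, n_intervals = 20) {
  stopifnot(feature %in% names(data))
  if (n_intervals < 2) stop("n_intervals must be >= 2")
  x <- data[[feature]]
  if (!is.numeric(x)) stop("AL profiles require a numeric feature")
  pred <- model_predictor(model)
  edges <- unique(stats::quantile(x, probs = seq(0, 1,
                                                 length.out = n_intervals + 1),
                                  names = FALSE, type = 7))
  if (length(edges) < n_intervals + 1)
    message("al_profile: ", n_intervals + 1 - length(edges),
            " empty interval(s) merged with neighbours")
  if (length(edges) < 2) stop("constant feature")
  K <- length(edges) - 1
  bin <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = K)
  effects <- numeric(K)
  for (k in seq_len(K)) {
    rows <- which(bin == k)
    if (!length(rows)) { effects[k] <- 0; next }
    hi <- data[rows, , drop = FALSE]; hi[[feature]] <- edges[k + 1]
    lo <- data[rows, , drop = FALSE]; lo[[feature]] <- edges[k]
    p <- pred(rbind(hi, lo))
    effects[k] <- mean(p[seq_along(rows)] - p[-seq_along(rows)])
  }
  v <- c(0, cumsum(effects))
  w <- c(0, counts) / sum(counts)
  yhat <- v - sum(w * v)
  new_profile(feature, edges, yhat, "AL", weights = w)
}

#' Two-variable partial-dependence surface
#'
#' Marginal average prediction on the joint grid of two continuous
#' features; the tool for visualising interactions (for an additive
#' model every 2x2 cross-difference of the surface vanishes).
#'
#' @inheritParams pd_profile
#' @param feature_a,feature_b Continuous feature names.
#' @param grid_sizes Length-2 vector of quantile grid sizes.
#' @return A `xai_profile_2d` list: `feature_a`, `feature_b`, `grid_a`,
#'   `grid_b`, `yhat` (matrix `length(grid_a) x length(grid_b)`).
#' @export
pd_profile_2d <- function(model, data, feature_a, feature_b,
                          grid_sizes = c(21, 21)) {
  stopifnot(feature_a %in% names(data), feature_b %in% names(data))
  if (!is.numeric(data[[feature_a]]) || !is.numeric(data[[feature_b]]))
    stop("both features must be continuous")
  pred <- model_predictor(model)
  ga <- profile_grid(data[[feature_a]], grid_sizes[1])
  gb <- profile_grid(data[[feature_b]], grid_sizes[2])
  yhat <- matrix(NA_real_, length(ga), length(gb))
  for (i in seq_along(ga)) {
    d <- data
    d[[feature_a]] <- ga[i]
    yhat[i, ] <- marginal_means(pred, d, feature_b, gb)
  }
  structure(list(feature_a = feature_a, feature_b = feature_b,
                 grid_a = ga, grid_b = gb, yhat = yhat),
            class = "xai_profile_2d")
}

#' Break-down attribution of a single prediction
#'
#' Decomposes one prediction into an intercept (the mean model
#' prediction over the reference data) plus one additive contribution
#' per feature, obtained by sequentially conditioning on the
#' observation's feature values: the contribution of the j-th feature in
#' the ordering is the change in the mean prediction when that feature
#' is fixed on top of the already-fixed set (expectations are empirical
#' means over the reference rows with the fixed columns substituted).
#' The contributions telescope, so
#' `intercept + sum(deltas) == prediction` exactly.
#'
#' The default ordering is greedy: each step fixes the feature with the
#' largest absolute change in the expected prediction given the current
#' set, ties broken lexicographically. Pass `order` for a fixed
#' ordering (required for cross-unit comparability in maps).
#'
#' @param model Fitted model or prediction function.
#' @param data Reference data frame (feature columns).
#' @param observation One-row data frame with the unit's feature values.
#' @param order Optional character vector fixing the conditioning order.
#' @param features Features to attribute (default: all columns of
#'   `data`; remaining columns are never substituted).
#' @return A `break_down` object: `unit_id`, `intercept`,
#'   `contributions` (data frame `feature`, `value`, `delta` in
#'   conditioning order), `prediction`, `ordering_rule`.
#' @export
break_down <- function(model, data, observation, order = NULL,
                       features = NULL) {
  pred <- model_predictor(model)
  if (is.null(features)) features <- names(data)
  miss <- setdiff(features, names(observation))
  if (length(miss))
    stop("observation lacks feature(s): ", paste(miss, collapse = ", "))
  if (!is.null(order)) {
    bad <- setdiff(order, features)
    if (length(bad))
      stop("order names unknown feature(s): ", paste(bad, collapse = ", "))
    if (length(setdiff(features, order)))
      features <- order  # attribute exactly the ordered set
  }

  n <- nrow(data)
  set_col <- function(d, f) {
    v <- observation[[f]]
    d[[f]] <- if (is.factor(data[[f]]))
      factor(as.character(v), levels = levels(data[[f]])) else v
    d
  }
  mean_blocks <- function(frames) {
    p <- pred(do.call(rbind, frames))
    vapply(seq_along(frames), function(k)
      mean(p[((k - 1) * n + 1):(k * n)]), 0)
  }

  intercept <- mean(pred(data))
  cur <- data
  m_prev <- intercept
  ordered <- character(0)
  deltas <- numeric(0)
  if (!is.null(order)) {
    frames <- list()
    d <- cur
    for (f in order) { d <- set_col(d, f); frames[[length(frames) + 1]] <- d }
    ms <- mean_blocks(frames)
    ordered <- order
    deltas <- diff(c(intercept, ms))
    m_prev <- ms[length(ms)]
    rule <- "fixed"
  } else {
    remaining <- sort(features)
    while (length(remaining)) {
      ms <- mean_blocks(lapply(remaining, function(f) set_col(cur, f)))
      gain <- abs(ms - m_prev)
      pickv <- max(gain)
      pick <- remaining[gain >= pickv - 1e-12][1]  # lexicographic tie-break
      k <- match(pick, remaining)
      ordered <- c(ordered, pick)
      deltas <- c(deltas, ms[k] - m_prev)
      m_prev <- ms[k]
      cur <- set_col(cur, pick)
      remaining <- setdiff(remaining, pick)
    }
    rule <- "greedy"
  }
  contributions <- data.frame(
    feature = ordered,
    value = vapply(ordered, function(f) as.character(observation[[f]]), ""),
    delta = deltas, stringsAsFactors = FALSE)
  structure(list(unit_id = if ("unit_id" %in% names(observation))
                   as.character(observation$unit_id) else NA_character_,
                 intercept = intercept, contributions = contributions,
                 prediction = m_prev, ordering_rule = rule),
            class = "break_down")
}

#' @export
print.break_down <- function(x, ...) {
  cat("Break-down attribution",
      if (!is.na(x$unit_id)) paste0(" for unit ", x$unit_id), "\n", sep = "")
  cat(sprintf("intercept (mean prediction): %.4f\n", x$intercept))
  df <- x$contributions
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %+9.4f  %s = %s\n", df$delta[i], df$feature[i], df$value[i]))
  cat(sprintf("prediction: %.4f  (ordering: %s)\n", x$prediction,
              x$ordering_rule))
  invisible(x)
}
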