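#' Getis-Ord Gi* hotspot statistic
#'
#' For each unit i, the Gi* z-score contrasts the weighted sum of the
#' variable over i's neighbourhood (including i itself, the "star"
#' convention) with its expectation under spatial randomness:
#' \deqn{G_i^* = \frac{\sum_j w_{ij} x_j - \bar{X} \sum_j w_{ij}}
#'   {S \sqrt{[n \sum_j w_{ij}^2 - (\sum_j w_{ij})^2]/(n-1)}}}
#' with \eqn{\bar{X}} the global mean and
#' \eqn{S = \sqrt{\sum_j x_j^2/n - \bar{X}^2}}. Large positive z-scores
#' mark hot spots (clusters of high rates), large negative z-scores cold
#' spots. A two-sided normal p-value and the seven-level Gi-bin
#' classification ([classify_gi_bins()]) are attached.
#'
#' @param values Numeric vector, one value per unit of `W`.
#' @param W A `spatial_weights` object with `include_self = TRUE`.
#' @return A `hotspot_result` data frame: `unit_id`, `gi_z`, `p_value`,
#'   `gi_bin`.
#' @export
gi_star <- function(values, W) {
  stopifnot(inherits(W, "spatial_weights"))
  n <- length(W$ids)
  if (length(values) != n) stop("values must have one entry per unit")
  if (n < 3) stop("need at least 3 units")
  if (!W$include_self)
    stop("Gi* requires weights with include_self = TRUE (the star convention)")
  xbar <- mean(values)
  S <- sqrt(sum(values^2) / n - xbar^2)
  if (S <= .Machine$double.eps^0.5 * max(1, abs(xbar))) {
    warning("zero-variance field: all Gi* z-scores set to 0")
    z <- rep(0, n)
  } else {
    z <- vapply(seq_len(n), function(i) {
      w <- W$weights[[i]]
      wx <- sum(w * values[W$neighbors[[i]]])
      sw <- sum(w); sw2 <- sum(w^2)
      denom <- S * sqrt((n * sw2 - sw^2) / (n - 1))
      if (denom == 0) 0 else (wx - xbar * sw) / denom
    }, 0)
  }
  out <- data.frame(unit_id = W$ids, gi_z = z,
                    p_value = 2 * stats::pnorm(-abs(z)),
                    gi_bin = classify_gi_bins(z),
                    stringsAsFactors = FALSE)
  class(out) <- c("hotspot_result", "data.frame")
  out
}

#' Seven-level Gi-bin classification
#'
#' Classical two-sided normal cutoffs at 90/95/99% confidence:
#' `|z| >= 2.576` gives bins +/-3, `1.960 <= |z| < 2.576` +/-2,
#' `1.645 <= |z| < 1.960` +/-1, anything smaller 0. The sign of the bin
#' follows the sign of the z-score. No multiple-testing correction is
#' applied.
#'
#' @param z_values Numeric vector of Gi* z-scores.
#' @return Integer vector in `{-3, ..., 3}`.
#' @export
classify_gi_bins <- function(z_values) {
  a <- abs(z_values)
  mag <- ifelse(a >= 2.576, 3L, ifelse(a >= 1.960, 2L, ifelse(a >= 1.645, 1L, 0L)))
  as.integer(sign(z_values)) * mag
}

#' Bivariate local Moran's I
#'
#' Per-unit product of the standardized first variable at i and the
#' spatial lag (weighted neighbour average) of the standardized second
#' variable: \eqn{I_i = z_{x,i} \sum_j w_{ij} z_{y,j}}. Significance is
#' assessed by conditional permutation: holding unit i fixed, the
#' z-scored `y` values of the other n-1 units are permuted and the lag
#' recomputed; the two-sided pseudo p-value is
#' `(#{|I_perm| >= |I_obs|} + 1) / (n_perm + 1)`. Significant units are
#' classified HH/HL/LH/LL from the signs of `z_x` and the lag.
#'
#' @param x,y Numeric vectors (unit order of `W`).
#' @param W Row-standardized `spatial_weights` without self-neighbours.
#' @param n_perm Number of conditional permutations (default 999).
#' @param seed Optional integer seed.
#' @param alpha Significance level for cluster labelling.
#' @return A `bivariate_lmi` data frame: `unit_id`, `I_i`, `lag_zy`,
#'   `perm_p`, `cluster`.
#' @export
bivariate_local_moran <- function(x, y, W, n_perm = 999, seed = NULL,
                                  alpha = 0.05) {
  stopifnot(inherits(W, "spatial_weights"))
  n <- length(W$ids)
  if (length(x) != n || length(y) != n) stop("x and y must match W in length")
  if (W$include_self) stop("local Moran weights must not include self")
  if (W$standardization != "row") stop("W must be row-standardized")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  zx <- as.numeric(scale(x)); zy <- as.numeric(scale(y))
  lag <- vapply(seq_len(n), function(i)
    sum(W$weights[[i]] * zy[W$neighbors[[i]]]), 0)
  I <- zx * lag

  perm <- function() {
    p <- numeric(n)
    for (i in seq_len(n)) {
      k <- length(W$neighbors[[i]])
      if (k == 0) { p[i] <- 1; next }
      pool <- zy[-i]
      w <- W$weights[[i]]
      draws <- matrix(pool[replicate(n_perm, sample.int(n - 1, k))], nrow = k)
      Iperm <- zx[i] * colSums(w * draws)
      p[i] <- (sum(abs(Iperm) >= abs(I[i])) + 1) / (n_perm + 1)
    }
    p
  }
  perm_p <- if (is.null(seed)) perm() else withr::with_seed(seed, perm())

  cluster <- rep("ns", n)
  sig <- perm_p <= alpha
  cluster[sig & zx > 0 & lag > 0] <- "HH"
  cluster[sig & zx > 0 & lag < 0] <- "HL"
  cluster[sig & zx < 0 & lag > 0] <- "LH"
  cluster[sig & zx < 0 & lag < 0] <- "LL"
  out <- data.frame(unit_id = W$ids, I_i = I, lag_zy = lag,
                    perm_p = perm_p, cluster = cluster,
                    stringsAsFactors = FALSE)
  class(out) <- c("bivariate_lmi", "data.frame")
  out
}

#' Geodetector q-statistic (factor detector)
#'
#' Measures stratified spatial heterogeneity: how much of the variance
#' of a variable is explained by a stratification of the study area,
#' \deqn{q = 1 - \frac{\sum_h N_h \sigma_h^2}{N \sigma^2} = 1 - SSW/SST,}
#' ranging from 0 (strata uninformative) to 1 (variable constant within
#' strata). Significance uses the geodetector noncentral-F test:
#' `F = ((N-L)/(L-1)) * q/(1-q)` with noncentrality
#' \eqn{\lambda = \frac{1}{\sigma^2}\left[\sum_h \bar{y}_h^2 -
#' \frac{(\sum_h \sqrt{N_h}\,\bar{y}_h)^2}{N}\right]}.
#'
#' @param values Numeric response vector.
#' @param strata_labels Stratum label per observation (factor/character/
#'   integer); every stratum must be nonempty.
#' @return A `q_stat` list: `q`, `f_stat`, `p_value`, `strata_count`,
#'   `strata_sizes`.
#' @export
q_statistic <- function(values, strata_labels) {
  if (length(values) != length(strata_labels))
    stop("values and strata_labels differ in length")
  if (length(values) < 2) stop("need at least 2 observations")
  if (anyNA(values) || anyNA(strata_labels)) stop("missing values not allowed")
  g <- factor(strata_labels)
  g <- droplevels(g)
  N <- length(values)
  L <- nlevels(g)
  sst <- sum((values - mean(values))^2)
  if (sst == 0) stop("q-statistic undefined: values are constant (SST = 0)")
  means <- tapply(values, g, mean)
  sizes <- as.integer(table(g))
  ssw <- sum(tapply(values, g, function(v) sum((v - mean(v))^2)))
  q <- 1 - ssw / sst
  if (L == 1) {
    f <- NA_real_; p <- NA_real_
  } else {
    sigma2 <- stats::var(values)
    # noncentrality vanishes when stratum means are homogeneous (and sizes
    # equal); note the first term is unweighted by stratum size
    lambda <- (sum(means^2) - sum(sqrt(sizes) * means)^2 / N) / sigma2
    f <- ((N - L) / (L - 1)) * q / (1 - q)
    # pnbeta warns about precision when the tail probability underflows;
    # immaterial at these magnitudes
    p <- suppressWarnings(stats::pf(f, df1 = L - 1, df2 = N - L,
                                    ncp = lambda, lower.tail = FALSE))
  }
  structure(list(q = q, f_stat = f, p_value = p, strata_count = L,
                 strata_sizes = sizes),
            class = "q_stat")
}

#' @export
print.q_stat <- function(x, ...) {
  cat(sprintf("q-statistic: %.4f (L = %d strata, N = %d)\n",
              x$q, x$strata_count, sum(x$strata_sizes)))
  if (!is.na(x$f_stat))
    cat(sprintf("noncentral-F = %.3f, p = %.4g\n", x$f_stat, x$p_value))
  invisible(x)
}

#' Discretize a continuous factor into strata
#'
#' Quantile slicing assigns near-equal-size strata (sizes differing by
#' at most one when values are distinct); ties at a boundary are
#' resolved to the lower stratum. Equal-interval slicing cuts the range
#' into `k_strata` equal-width bins.
#'
#' @param values Numeric vector.
#' @param k_strata Number of strata (>= 2).
#' @param method `"quantile"` (default) or `"equal_interval"`.
#' @return Integer stratum labels in `1:k_strata`.
#' @export
discretize_for_q <- function(values, k_strata = 5,
                             method = c("quantile", "equal_interval")) {
  method <- match.arg(method)
  if (k_strata < 2) stop("k_strata must be >= 2")
  if (length(unique(values)) < k_strata)
    stop("fewer distinct values than k_strata")
  if (method == "quantile") {
    r <- rank(values, ties.method = "min")
    as.integer(ceiling(r * k_strata / length(values)))
  } else {
    br <- seq(min(values), max(values), length.out = k_strata + 1)
    as.integer(cut(values, breaks = br, include.lowest = TRUE))
  }
}

#' q-statistic table over a set of risk factors
#'
#' Computes the factor-detector q for each named factor against the
#' response, discretizing continuous factors with [discretize_for_q()]
#' and using categorical factors as-is; rows are sorted by decreasing q
#' (the layout of a stratified-heterogeneity summary table).
#'
#' @param table A `county_table` with a response column.
#' @param response Response column name.
#' @param factors Character vector of factor column names.
#' @param k_strata Strata count for continuous factors.
#' @return A data frame: `factor`, `q`, `p_value`.
#' @export
q_table <- function(table, response = "response", factors, k_strata = 5) {
  stopifnot(response %in% names(table), all(factors %in% names(table)))
  y <- table[[response]]
  rows <- lapply(factors, function(f) {
    v <- table[[f]]
    lab <- if (is.numeric(v)) discretize_for_q(v, k_strata) else v
    qs <- q_statistic(y, lab)
    data.frame(factor = f, q = qs$q, p_value = qs$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$q), , drop = FALSE]
}
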