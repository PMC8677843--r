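# Eigenvalues of a row-standardized weight matrix. When the weights are
# uniform within rows and the underlying binary relation is symmetric,
# W = D^-1 A is similar to the symmetric D^-1/2 A D^-1/2, so a fast
# symmetric eigendecomposition applies; otherwise fall back to the dense
# nonsymmetric solver.
weights_eigenvalues <- function(W) {
  n <- length(W$ids)
  uniform <- all(vapply(W$weights, function(w)
    !length(w) || max(abs(w - w[1])) < 1e-12, TRUE))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) A[i, W$neighbors[[i]]] <- 1
  if (uniform && isSymmetric(A)) {
    d <- rowSums(A)
    s <- ifelse(d > 0, 1 / sqrt(d), 0)
    S <- A * tcrossprod(s)
    eigen(S, symmetric = TRUE, only.values = TRUE)$values
  } else {
    ev <- eigen(weights_matrix(W), only.values = TRUE)$values
    if (is.complex(ev)) {
      if (max(abs(Im(ev))) > 1e-8)
        stop("weight matrix has genuinely complex eigenvalues")
      ev <- Re(ev)
    }
    ev
  }
}

prep_design_matrix <- function(X, add_intercept) {
  X <- as.matrix(X)
  has_const <- any(apply(X, 2, function(c) max(c) == min(c) & c[1] != 0))
  if (add_intercept && !has_const)
    X <- cbind(`(Intercept)` = 1, X)
  if (qr(X)$rank < ncol(X)) stop("singular design matrix X")
  X
}

#' Spatial lag and spatial error models (maximum likelihood)
#'
#' Fits `y = rho W y + X beta + eps` (lag) or
#' `y = X beta + u, u = lambda W u + eps` (error) by maximum likelihood,
#' concentrating the log-likelihood over the autoregressive parameter
#' with the exact dense log-determinant
#' `log|I - rho W| = sum(log(1 - rho * ev))` from the eigenvalues of W
#' (desk-scale n). Coefficients are generalized least squares at the
#' optimum. Requires row-standardized weights, for which the
#' autoregressive parameter lies in `(1/min(ev), 1)`.
#'
#' @param y Numeric response.
#' @param X Covariate matrix (an intercept column is prepended unless
#'   one is present or `add_intercept = FALSE`).
#' @param W Row-standardized `spatial_weights`.
#' @param add_intercept Add an intercept column to `X`.
#' @return A `spatial_fit`: `model`, `rho` (or `lambda`), `betas`,
#'   `sigma_sq`, `loglik`, `loglik_at_zero`, `residuals`, `fitted`.
#' @export
fit_spatial_lag <- function(y, X, W, add_intercept = TRUE) {
  stopifnot(inherits(W, "spatial_weights"))
  if (W$standardization != "row") stop("W must be row-standardized")
  X <- prep_design_matrix(X, add_intercept)
  n <- length(y)
  stopifnot(nrow(X) == n, length(W$ids) == n)
  Wm <- weights_matrix(W)
  Wy <- as.numeric(Wm %*% y)
  ev <- weights_eigenvalues(W)
  f0 <- stats::lm.fit(X, y);  e0 <- f0$residuals
  fd <- stats::lm.fit(X, Wy); ed <- fd$residuals
  lo <- 1 / min(ev); hi <- 1 / max(ev)
  ll <- function(rho) {
    s2 <- sum((e0 - rho * ed)^2) / n
    sum(log(1 - rho * ev)) - n / 2 * (log(2 * pi * s2) + 1)
  }
  opt <- stats::optimize(ll, c(lo + 1e-6, hi - 1e-6), maximum = TRUE,
                         tol = 1e-8)
  rho <- opt$maximum
  fit <- stats::lm.fit(X, y - rho * Wy)
  res <- fit$residuals
  structure(list(model = "lag", rho = rho,
                 betas = stats::setNames(fit$coefficients, colnames(X)),
                 sigma_sq = sum(res^2) / n,
                 loglik = opt$objective, loglik_at_zero = ll(0),
                 residuals = res,
                 fitted = y - res,  # Xb + rho * Wy
                 n = n),
            class = "spatial_fit")
}

#' @rdname fit_spatial_lag
#' @export
fit_spatial_error <- function(y, X, W, add_intercept = TRUE) {
  stopifnot(inherits(W, "spatial_weights"))
  if (W$standardization != "row") stop("W must be row-standardized")
  X <- prep_design_matrix(X, add_intercept)
  n <- length(y)
  stopifnot(nrow(X) == n, length(W$ids) == n)
  Wm <- weights_matrix(W)
  Wy <- as.numeric(Wm %*% y)
  WX <- Wm %*% X
  ev <- weights_eigenvalues(W)
  lo <- 1 / min(ev); hi <- 1 / max(ev)
  ll <- function(lam) {
    ys <- y - lam * Wy
    Xs <- X - lam * WX
    rss <- sum(stats::lm.fit(Xs, ys)$residuals^2)
    sum(log(1 - lam * ev)) - n / 2 * (log(2 * pi * rss / n) + 1)
  }
  opt <- stats::optimize(ll, c(lo + 1e-6, hi - 1e-6), maximum = TRUE,
                         tol = 1e-8)
  lam <- opt$maximum
  fit <- stats::lm.fit(X - lam * WX, y - lam * Wy)
  beta <- stats::setNames(fit$coefficients, colnames(X))
  res <- y - as.numeric(X %*% beta)
  structure(list(model = "error", lambda = lam, betas = beta,
                 sigma_sq = sum(fit$residuals^2) / n,
                 loglik = opt$objective, loglik_at_zero = ll(0),
                 residuals = res, fitted = as.numeric(X %*% beta), n = n),
            class = "spatial_fit")
}

#' @export
print.spatial_fit <- function(x, ...) {
  par <- if (x$model == "lag") c(rho = x$rho) else c(lambda = x$lambda)
  cat("Spatial ", x$model, " model (ML), n = ", x$n, "\n", sep = "")
  cat(sprintf("%s = %.4f, sigma^2 = %.4f, logLik = %.2f\n",
              names(par), par, x$sigma_sq, x$loglik))
  cat("Coefficients:\n"); print(round(x$betas, 4))
  invisible(x)
}

#' @export
coef.spatial_fit <- function(object, ...) object$betas

#' Geographically weighted OLS
#'
#' Per-unit weighted least squares with Gaussian kernel weights
#' `exp(-d^2 / (2 bandwidth^2))` on centroid distances, yielding a
#' spatially varying coefficient surface.
#'
#' @param y Numeric response.
#' @param X Covariate matrix (intercept handled as in
#'   [fit_spatial_lag()]).
#' @param coords Two-column matrix of unit centroids.
#' @param bandwidth Kernel scale (> 0), in coordinate units.
#' @param add_intercept Add an intercept column.
#' @return A `gw_fit`: `betas` (n x p matrix), `fitted`, `residuals`,
#'   `bandwidth`, `kernel`.
#' @export
fit_gw_ols <- function(y, X, coords, bandwidth, add_intercept = TRUE) {
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  X <- prep_design_matrix(X, add_intercept)
  coords <- as.matrix(coords)
  n <- length(y); p <- ncol(X)
  stopifnot(nrow(X) == n, nrow(coords) == n)
  B <- matrix(NA_real_, n, p, dimnames = list(NULL, colnames(X)))
  for (i in seq_len(n)) {
    d2 <- (coords[, 1] - coords[i, 1])^2 + (coords[, 2] - coords[i, 2])^2
    w <- exp(-d2 / (2 * bandwidth^2))
    if (sum(w) < p)
      stop("effective sample at unit ", i, " (sum of weights ",
           signif(sum(w), 3), ") below the number of coefficients")
    B[i, ] <- stats::lm.wfit(X, y, w)$coefficients
  }
  fitted <- rowSums(X * B)
  structure(list(betas = B, fitted = fitted, residuals = y - fitted,
                 bandwidth = bandwidth, kernel = "gaussian", n = n),
            class = "gw_fit")
}

#' @export
print.gw_fit <- function(x, ...) {
  cat("Geographically weighted OLS: n = ", x$n, ", gaussian bandwidth = ",
      signif(x$bandwidth, 4), "\n", sep = "")
  cat("Local coefficient ranges:\n")
  print(apply(x$betas, 2, range))
  invisible(x)
}

#' Leave-one-out bandwidth selection for GW-OLS
#'
#' Scores each candidate bandwidth by leave-one-out cross-validated
#' RMSE (the unit's own kernel weight set to zero) over a geometric
#' grid spanning the nearest-neighbour scale to the map extent, and
#' returns the minimizer.
#'
#' @inheritParams fit_gw_ols
#' @param bandwidths Optional candidate vector; default: 12 points,
#'   geometric, from the median nearest-neighbour distance to the
#'   extent diagonal.
#' @return The selected bandwidth, with the score table in attribute
#'   `cv`.
#' @export
select_bandwidth <- function(y, X, coords, bandwidths = NULL,
                             add_intercept = TRUE) {
  X <- prep_design_matrix(X, add_intercept)
  coords <- as.matrix(coords)
  n <- length(y); p <- ncol(X)
  D2 <- as.matrix(stats::dist(coords))^2
  if (is.null(bandwidths)) {
    nn <- sqrt(apply(D2 + diag(Inf, n), 1, min))
    lo <- stats::median(nn)
    hi <- sqrt(max(D2))
    bandwidths <- exp(seq(log(lo), log(hi), length.out = 12))
  }
  cv <- vapply(bandwidths, function(b) {
    err <- vapply(seq_len(n), function(i) {
      w <- exp(-D2[i, ] / (2 * b^2))
      w[i] <- 0
      if (sum(w) < p) return(NA_real_)
      beta <- stats::lm.wfit(X, y, w)$coefficients
      y[i] - sum(X[i, ] * beta)
    }, 0)
    if (anyNA(err)) Inf else sqrt(mean(err^2))
  }, 0)
  best <- bandwidths[which.min(cv)]
  attr(best, "cv") <- data.frame(bandwidth = bandwidths, cv_rmse = cv)
  best
}

#' Simulate a spatial lag process
#'
#' Draws `y = (I - rho W)^{-1} (X beta + eps)` with Gaussian noise —
#' the generating model of the spatial lag regression, used for
#' parameter-recovery checks.
#'
#' @param X Covariate matrix (no intercept column needed; pass one to
#'   include it).
#' @param beta Coefficient vector matching `ncol(X)`.
#' @param rho Autoregressive parameter, |rho| < 1.
#' @param W Row-standardized `spatial_weights`.
#' @param noise_sd Noise standard deviation.
#' @param seed Optional integer seed.
#' @return Numeric response vector.
#' @export
simulate_lag_process <- function(X, beta, rho, W, noise_sd = 1, seed = NULL) {
  stopifnot(abs(rho) < 1, W$standardization == "row")
  n <- nrow(X)
  draw <- function() stats::rnorm(n, 0, noise_sd)
  eps <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  A <- diag(n) - rho * weights_matrix(W)
  as.numeric(solve(A, as.matrix(X) %*% beta + eps))
}
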