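# Independent brute-force oracles, written directly from the textbook
# formulas with dense matrices and explicit loops. They deliberately share
# no code with the package internals.

# Global Moran's I with binary rook weights on a lattice table.
moran_I_oracle <- function(values, table) {
  n <- length(values)
  xc <- values - mean(values)
  W <- (abs(outer(table$row, table$row, "-")) +
          abs(outer(table$col, table$col, "-"))) == 1
  (n / sum(W)) * sum(W * outer(xc, xc)) / sum(xc^2)
}

# Getis-Ord Gi* z-scores evaluated directly from the formula, given a
# dense weight matrix with self weights included.
gi_star_oracle <- function(values, Wmat) {
  n <- length(values)
  xbar <- mean(values)
  S <- sqrt(sum(values^2) / n - xbar^2)
  vapply(seq_len(n), function(i) {
    w <- Wmat[i, ]
    (sum(w * values) - xbar * sum(w)) /
      (S * sqrt((n * sum(w^2) - sum(w)^2) / (n - 1)))
  }, 0)
}

# Bivariate local Moran with a dense row-standardized weight matrix.
lmi_oracle <- function(x, y, Wmat) {
  zx <- (x - mean(x)) / sd(x)
  zy <- (y - mean(y)) / sd(y)
  as.numeric(zx * (Wmat %*% zy))
}

# q-statistic via one-way ANOVA R^2 (an independent base-R route).
q_oracle <- function(values, strata) {
  summary(stats::lm(values ~ factor(strata)))$r.squared
}

# Dense binary contiguity matrix straight from lattice indices.
contiguity_oracle <- function(table, rule = "queen", include_self = FALSE) {
  n <- nrow(table)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dr <- abs(table$row[i] - table$row[j])
    dc <- abs(table$col[i] - table$col[j])
    M[i, j] <- if (i == j) as.numeric(include_self)
    else if (rule == "rook") as.numeric(dr + dc == 1)
    else as.numeric(dr <= 1 && dc <= 1)
  }
  M
}

# Small fully simulated study area shared across tests.
small_counties <- function(nrows = 12, ncols = 12, seed = 42, ...) {
  simulate_counties(nrows, ncols, seed = seed, ...)
}

# Feature columns of a simulated table.
feature_cols <- function(tab)
  setdiff(names(tab), c("unit_id", "row", "col", "x", "y", "response",
                        "gi_bin", "partition"))
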