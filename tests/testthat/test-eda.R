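test_that("Gi* matches a direct evaluation of the formula", {
  tab <- make_lattice(5, 5)
  vals <- rep(1, 25)
  centre <- which(tab$row == 3 & tab$col == 3)
  vals[centre] <- 10
  W <- contiguity_weights(tab, "queen", include_self = TRUE)
  hs <- gi_star(vals, W)
  oracle <- gi_star_oracle(vals, contiguity_oracle(tab, "queen", TRUE))
  expect_equal(hs$gi_z, oracle, tolerance = 1e-10)
  expect_gt(hs$gi_z[centre], 0)  # elevated neighbourhood sum
  expect_true(all(hs$p_value > 0 & hs$p_value <= 1))
})

test_that("constant fields yield zero Gi* everywhere", {
  tab <- make_lattice(4, 4)
  W <- contiguity_weights(tab, "queen", include_self = TRUE)
  expect_warning(hs <- gi_star(rep(3.7, 16), W), "zero-variance")
  expect_true(all(hs$gi_z == 0))
  expect_true(all(hs$gi_bin == 0))
})

test_that("Gi* insists on star weights", {
  tab <- make_lattice(4, 4)
  expect_error(gi_star(rnorm(16), contiguity_weights(tab, "queen")),
               "include_self")
})

test_that("Gi-bins follow the 90/95/99% two-sided cutoffs", {
  z <- c(3.0, 2.576, 2.0, 1.96, 1.7, 1.645, 0.5, 0, -0.5, -1.645, -2.0, -3.0)
  expect_equal(classify_gi_bins(z),
               c(3L, 3L, 2L, 2L, 1L, 1L, 0L, 0L, 0L, -1L, -2L, -3L))
  # bin sign equals z sign whenever |z| >= 1.645
  zz <- seq(-4, 4, by = 0.05)
  b <- classify_gi_bins(zz)
  expect_true(all(sign(b[abs(zz) >= 1.645]) == sign(zz[abs(zz) >= 1.645])))
  expect_true(all(b[abs(zz) < 1.645] == 0))
})

test_that("bivariate local Moran matches the direct computation", {
  tab <- make_lattice(4, 4)
  W <- row_standardize(contiguity_weights(tab, "rook"))
  set.seed(31)
  x <- rnorm(16); y <- rnorm(16)
  res <- bivariate_local_moran(x, y, W, n_perm = 99, seed = 1)
  expect_equal(res$I_i, lmi_oracle(x, y, weights_matrix(W)),
               tolerance = 1e-12)
  expect_true(all(res$perm_p >= 1 / 100))  # permutation floor at n_perm = 99
  expect_true(all(res$cluster[res$perm_p > 0.05] == "ns"))
})

test_that("a checkerboard is pure negative local association with itself", {
  tab <- make_lattice(6, 6)
  chk <- ifelse((tab$row + tab$col) %% 2 == 0, 1, -1)
  W <- row_standardize(contiguity_weights(tab, "rook"))
  res <- bivariate_local_moran(chk, chk, W, n_perm = 99, seed = 2)
  expect_true(all(res$I_i < 0))
})

test_that("local Moran rejects bad inputs", {
  tab <- make_lattice(4, 4)
  Wr <- row_standardize(contiguity_weights(tab, "rook"))
  expect_error(bivariate_local_moran(rep(1, 16), rnorm(16), Wr), "variance")
  expect_error(
    bivariate_local_moran(rnorm(16), rnorm(16),
                          contiguity_weights(tab, "rook")),
    "row-standardized")
  star <- row_standardize(contiguity_weights(tab, "rook",
                                             include_self = TRUE))
  expect_error(bivariate_local_moran(rnorm(16), rnorm(16), star), "self")
})

test_that("q-statistic reproduces hand-computed and limiting cases", {
  # hand computation: SSW = 4, SST = 125.5
  qs <- q_statistic(c(1, 2, 3, 10, 11, 12), c("A", "A", "A", "B", "B", "B"))
  expect_equal(qs$q, 1 - 4 / 125.5, tolerance = 1e-12)
  expect_lt(qs$p_value, 0.05)

  # single stratum: q = 0 by definition
  expect_equal(q_statistic(c(1, 5, 9), c("A", "A", "A"))$q, 0)

  # constant within strata, different means: q = 1
  expect_equal(q_statistic(c(2, 2, 7, 7), c("A", "A", "B", "B"))$q, 1)

  expect_error(q_statistic(rep(4, 6), rep(c("A", "B"), 3)), "SST")
})

test_that("q agrees with the one-way ANOVA R^2 oracle on random strata", {
  set.seed(5)
  for (r in 1:5) {
    y <- rnorm(60)
    s <- sample(letters[1:4], 60, replace = TRUE)
    expect_equal(q_statistic(y, s)$q, q_oracle(y, s), tolerance = 1e-10)
  }
})

test_that("q under uninformative strata is near zero and grows under splits", {
  set.seed(9)
  y <- rnorm(5000)
  qs <- replicate(20, q_statistic(y, sample(1:5, 5000, replace = TRUE))$q)
  expect_lt(mean(qs), 0.02)

  # subdividing a stratum can never decrease q
  s <- rep(1:2, each = 2500)
  q2 <- q_statistic(y, s)$q
  s4 <- s * 10 + rep(rep(1:2, each = 1250), 2)
  expect_gte(q_statistic(y, s4)$q, q2)
})

test_that("quantile discretization yields balanced strata with a lower tie rule", {
  v <- sample(seq(0.01, 1, 0.01))  # 100 distinct values
  lab <- discretize_for_q(v, 5, "quantile")
  expect_equal(unname(table(lab)), rep(20L, 5), ignore_attr = TRUE)

  expect_equal(discretize_for_q(1:10, 2), rep(1:2, each = 5))

  # ties straddling a boundary land together in the lower stratum
  vt <- c(1, 2, 3, 4, 5, 5, 7, 8, 9, 10)
  lt <- discretize_for_q(vt, 2)
  expect_equal(lt[vt == 5], c(1L, 1L))

  expect_error(discretize_for_q(c(1, 1, 2), 3), "distinct")
  expect_error(discretize_for_q(1:10, 1), ">= 2")
})

test_that("oracle equivalence holds on random 6x6 lattices", {
  tab <- make_lattice(6, 6)
  Wstar <- contiguity_weights(tab, "queen", include_self = TRUE)
  Wrow <- row_standardize(contiguity_weights(tab, "queen"))
  Mstar <- contiguity_oracle(tab, "queen", TRUE)
  Mrow <- weights_matrix(Wrow)
  set.seed(17)
  for (r in 1:5) {
    x <- rnorm(36); y <- rnorm(36)
    expect_equal(gi_star(x, Wstar)$gi_z, gi_star_oracle(x, Mstar),
                 tolerance = 1e-10)
    expect_equal(bivariate_local_moran(x, y, Wrow, n_perm = 19)$I_i,
                 lmi_oracle(x, y, Mrow), tolerance = 1e-10)
    s <- sample(1:3, 36, replace = TRUE)
    expect_equal(q_statistic(x, s)$q, q_oracle(x, s), tolerance = 1e-10)
  }
})
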