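# Linear predictors with known coefficients are the workhorse here:
# every explainer has an analytic answer for them.
lin_model <- function(beta, intercept = 0) {
  function(nd) intercept + as.matrix(nd[, names(beta), drop = FALSE]) %*% beta
}

test_that("permutation importance isolates signal from noise features", {
  set.seed(1)
  n <- 2000
  d <- data.frame(signal = rnorm(n), noise = rnorm(n))
  d$y <- 3 * d$signal + rnorm(n, 0, 0.5)
  m <- lin_model(c(signal = 3))
  imp <- permutation_importance(m, d, "y", features = c("signal", "noise"),
                                n_repeats = 20, seed = 2)
  noise_row <- imp[imp$feature == "noise", ]
  expect_gt(noise_row$dropout_ratio, 0.9)
  expect_lt(noise_row$dropout_ratio, 1.1)
  expect_gt(imp[imp$feature == "signal", "dropout_ratio"], 1)
  expect_equal(imp$feature[1], "signal")  # ranked by permuted loss

  imp2 <- permutation_importance(m, d, "y", features = c("signal", "noise"),
                                 n_repeats = 20, seed = 2)
  expect_identical(imp, imp2)  # seeded determinism
})

test_that("zero baseline loss is flagged but differences still reported", {
  d <- data.frame(a = rnorm(50))
  d$y <- 2 * d$a
  expect_warning(
    imp <- permutation_importance(lin_model(c(a = 2)), d, "y",
                                  features = "a", n_repeats = 3, seed = 1),
    "perfect")
  expect_true(is.na(imp$dropout_ratio))
  expect_gt(imp$dropout_difference, 0)
})

test_that("PD profiles are exact for linear and constant models", {
  set.seed(3)
  d <- data.frame(a = runif(500, 0, 10), b = rnorm(500))
  pd <- pd_profile(lin_model(c(a = 2, b = 1), 5), d, "a", grid_size = 21)
  slopes <- diff(pd$yhat) / diff(pd$grid)
  expect_equal(slopes, rep(2, length(slopes)), tolerance = 1e-10)

  flat <- pd_profile(function(nd) rep(7, nrow(nd)), d, "a")
  expect_true(all(flat$yhat == 7))
  expect_true(all(diff(flat$grid) > 0))
  expect_error(pd_profile(lin_model(c(a = 1)), data.frame(a = rep(1, 10)),
                          "a"), "constant")
})

test_that("PD recovers the generator's stored additive truth", {
  tab <- make_lattice(45, 45)
  tab <- simulate_risk_factors(tab, 3, list(cont_feature("u", 0, 10),
                                            cont_feature("v", -5, 5)),
                               seed = 4)
  eff <- effect_spec(intercept = 1, additive = list(
    u = list(shape = "linear", coef = 1.2),
    v = list(shape = "threshold_linear", coef = 2, threshold = 0)))
  tab <- simulate_response(tab, eff)
  m <- lm(response ~ u + pmax(v, 0), data = tab)
  truth_u <- attr(tab, "effect_fns")$u
  pd <- pd_profile(m, as.data.frame(tab), "u", grid_size = 31)
  dev <- (pd$yhat - truth_u(pd$grid))
  dev <- dev - mean(dev)  # PD is defined up to an additive constant
  expect_lt(max(abs(dev)), 0.02 * diff(range(tab$response)))
})

test_that("LD reduces to PD when the neighbourhood is everything", {
  set.seed(5)
  d <- data.frame(a = runif(300), b = runif(300))
  m <- function(nd) nd$a * 2 + nd$b
  ld <- ld_profile(m, d, "a", grid_size = 11, neighborhood_frac = 1)
  pd <- pd_profile(m, d, "a", grid_size = 11)
  expect_equal(ld$yhat, pd$yhat, tolerance = 1e-12)

  flat <- ld_profile(function(nd) rep(1, nrow(nd)), d, "a",
                     neighborhood_frac = 0.2)
  expect_true(all(flat$yhat == 1))
})

test_that("LD approximates PD under independent features", {
  set.seed(6)
  n <- 4000
  d <- data.frame(a = runif(n, 0, 1), b = runif(n, 0, 1))
  m <- function(nd) 3 * nd$a + 2 * nd$b^2
  ld <- ld_profile(m, d, "a", grid_size = 15, neighborhood_frac = 0.1)
  pd <- pd_profile(m, d, "a", grid_size = 15)
  preds <- m(d)
  expect_lt(max(abs(ld$yhat - pd$yhat)), 0.05 * diff(range(preds)))
})

test_that("AL profiles are unbiased for linear models under correlation", {
  set.seed(7)
  n <- 2000
  a <- rnorm(n)
  b <- 0.9 * a + sqrt(1 - 0.81) * rnorm(n)  # strongly correlated
  d <- data.frame(a = a, b = b)
  beta <- 1.7
  al <- al_profile(lin_model(c(a = beta, b = -2)), d, "a", n_intervals = 20)
  slope <- coef(lm(al$yhat ~ al$grid))[2]
  expect_lt(abs(slope - beta) / beta, 0.02)

  # the profile is mean-centred under its empirical weights
  expect_lt(abs(sum(attr(al, "weights") * al$yhat)), 1e-10)

  # a model that ignores the feature has an identically zero AL profile
  al0 <- al_profile(function(nd) 4 * nd$b, d, "a", n_intervals = 10)
  expect_true(all(abs(al0$yhat) < 1e-12))
})

test_that("AL and PD are parallel for an additive fitted model", {
  tab <- small_counties(30, 30, seed = 8)
  m <- lm(response ~ smoking + poverty + pm25 + elevation, data = tab)
  al <- al_profile(m, as.data.frame(tab), "smoking", n_intervals = 20)
  pd <- pd_profile(m, as.data.frame(tab), "smoking", grid_size = 21)
  al_on_pd <- approx(al$grid, al$yhat, xout = pd$grid, rule = 2)$y
  gap <- al_on_pd - pd$yhat
  expect_lt(sd(gap), 0.02 * diff(range(fitted(m))))
})

test_that("2D partial dependence detects additivity and the threshold interaction", {
  set.seed(9)
  d <- data.frame(a = runif(400, 0, 10), b = runif(400, 0, 10))
  add <- pd_profile_2d(lin_model(c(a = 1, b = 2)), d, "a", "b",
                       grid_sizes = c(8, 8))
  cross <- diff(t(diff(add$yhat)))  # all 2x2 cross-differences
  expect_lt(max(abs(cross)), 1e-10)

  # argument order only transposes the surface
  ba <- pd_profile_2d(lin_model(c(a = 1, b = 2)), d, "b", "a",
                      grid_sizes = c(8, 8))
  expect_equal(add$yhat, t(ba$yhat), tolerance = 1e-12)

  # threshold interaction: poverty slope appears only above smoking = 30
  tab <- small_counties(30, 30, seed = 10)
  m <- function(nd) 1 * nd$smoking + 0.35 * nd$poverty * (nd$smoking > 30)
  p2 <- pd_profile_2d(m, as.data.frame(tab), "smoking", "poverty",
                      grid_sizes = c(15, 9))
  pov_slope <- apply(p2$yhat, 1, function(r) diff(range(r)))
  lo <- p2$grid_a < 30; hi <- p2$grid_a > 30
  expect_lt(max(pov_slope[lo]), 1e-10)
  expect_gt(min(pov_slope[hi]), 1)
})

test_that("break-down is additive and analytic for linear predictors", {
  set.seed(11)
  d <- data.frame(a = rnorm(200), b = rnorm(200), c = rnorm(200))
  beta <- c(a = 2, b = -1, c = 0.5)
  m <- lin_model(beta, 10)
  obs <- d[17, ]

  for (ord in list(NULL, c("a", "b", "c"), c("c", "b", "a"))) {
    bd <- break_down(m, d, obs, order = ord)
    expect_equal(bd$intercept + sum(bd$contributions$delta), bd$prediction,
                 tolerance = 1e-9)
    # delta_j = beta_j * (x_j - mean(x_j)) for every ordering
    for (f in names(beta)) {
      expect_equal(bd$contributions$delta[bd$contributions$feature == f],
                   beta[[f]] * (obs[[f]] - mean(d[[f]])),
                   tolerance = 1e-10)
    }
  }
  expect_equal(break_down(m, d, obs)$prediction, as.numeric(m(obs)),
               tolerance = 1e-10)
})

test_that("greedy ordering equals exhaustive enumeration on a 3-feature toy", {
  set.seed(12)
  d <- data.frame(a = runif(60), b = runif(60), c = runif(60))
  m <- function(nd) 5 * nd$a * nd$b + 2 * nd$c + nd$b^2
  obs <- d[3, ]

  # brute force: among all candidate features at each step, pick the one
  # with the largest |change in expected prediction| (ties: name order)
  exp_fix <- function(fixed) {
    dd <- d
    for (f in fixed) dd[[f]] <- obs[[f]]
    mean(m(dd))
  }
  remaining <- c("a", "b", "c"); fixed <- character(0)
  while (length(remaining)) {
    gains <- vapply(remaining,
                    function(f) abs(exp_fix(c(fixed, f)) - exp_fix(fixed)), 0)
    pick <- remaining[order(-gains, remaining)][1]
    fixed <- c(fixed, pick)
    remaining <- setdiff(remaining, pick)
  }
  bd <- break_down(m, d, obs)
  expect_equal(bd$contributions$feature, fixed)
  expect_equal(bd$ordering_rule, "greedy")
})

test_that("break-down validates its inputs", {
  d <- data.frame(a = 1:5, b = 6:10)
  m <- lin_model(c(a = 1, b = 1))
  expect_error(break_down(m, d, data.frame(a = 1), order = "b"), "lacks")
  expect_error(break_down(m, d, d[1, ], order = c("a", "z")), "unknown")
})
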