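test_that("make_lattice builds a regular grid and rejects degenerate sizes", {
  tab <- make_lattice(3, 3, cell_size = 2)
  expect_equal(nrow(tab), 9)
  expect_false(anyDuplicated(tab$unit_id) > 0)
  centre <- tab[tab$row == 2 & tab$col == 2, ]
  expect_equal(c(centre$x, centre$y), c(3, 3))  # grid centre of a 3x3

  tab5 <- make_lattice(5, 5, cell_size = 1.5)
  d <- as.matrix(dist(cbind(tab5$x, tab5$y)))
  expect_true(min(d[d > 0]) >= 1.5)

  expect_error(make_lattice(2, 2), "3")
  expect_error(make_lattice(5, 2), "3")
})

test_that("risk-factor fields have the requested spatial autocorrelation", {
  tab <- make_lattice(40, 40)
  rough <- simulate_risk_factors(tab, spatial_range = 0.01,
                                 feature_specs = list(cont_feature("f", 0, 1)),
                                 seed = 1)
  smooth <- simulate_risk_factors(tab, spatial_range = 10,
                                  feature_specs = list(cont_feature("f", 0, 1)),
                                  seed = 1)
  # Moran's I oracle on a subsampled dense computation is O(n^2); 40x40 is fine
  expect_lt(abs(moran_I_oracle(rough$f, rough)), 0.05)
  expect_gt(moran_I_oracle(smooth$f, smooth), 0.5)
})

test_that("generators are pure functions of their seed", {
  tab <- make_lattice(10, 10)
  a <- simulate_risk_factors(tab, 3, seed = 7)
  b <- simulate_risk_factors(tab, 3, seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  ra <- simulate_response(a, seed = 9)
  rb <- simulate_response(b, seed = 9)
  expect_identical(ra$response, rb$response)
  expect_false(identical(ra$response,
                         simulate_response(a, seed = 10)$response))
})

test_that("ranges, levels and positivity hold under the default panel", {
  tab <- small_counties(20, 20, seed = 3)
  expect_false(anyNA(as.data.frame(tab)))
  expect_true(all(tab$smoking >= 5 & tab$smoking <= 45))
  expect_true(all(tab$response >= 0))
  for (f in c("radon_zone", "urban_rural", "coal"))
    expect_setequal(levels(droplevels(tab[[f]])), levels(tab[[f]]))
})

test_that("the response surface is exactly additive and noise closes the variance", {
  tab <- make_lattice(8, 8)
  tab <- simulate_risk_factors(tab, 2,
                               list(cont_feature("a", 0, 10)), seed = 1)
  eff <- effect_spec(intercept = 3,
                     additive = list(a = list(shape = "linear", coef = 2)))
  out <- simulate_response(tab, eff)
  expect_equal(out$response, 3 + 2 * out$a)

  # threshold-linear shape
  eff2 <- effect_spec(additive = list(
    a = list(shape = "threshold_linear", coef = 1.5, threshold = 5)))
  out2 <- simulate_response(tab, eff2)
  expect_equal(out2$response, 1.5 * pmax(out2$a - 5, 0))

  # analytic variance: var(noiseless) + noise_sd^2, default spec, n = 1600
  big <- simulate_counties(40, 40, seed = 11)
  analytic <- var(attr(big, "noiseless")) + default_effect_spec()$noise_sd^2
  expect_lt(abs(var(big$response) - analytic) / analytic, 0.10)
})

test_that("switching the interaction off leaves the additive part unchanged", {
  tab <- make_lattice(10, 10)
  tab <- simulate_risk_factors(tab, 3, list(cont_feature("smoking", 5, 45),
                                            cont_feature("poverty", 5, 50)),
                               seed = 2)
  base <- effect_spec(intercept = 10, additive = list(
    smoking = list(shape = "linear", coef = 1)), noise_sd = 1)
  with_int <- base
  with_int$interactions <- list(list(a = "smoking", b = "poverty",
                                     threshold_a = 30, coef = 0))
  expect_equal(simulate_response(tab, base, seed = 5)$response,
               simulate_response(tab, with_int, seed = 5)$response)
})

test_that("invalid effect specifications are rejected", {
  tab <- make_lattice(5, 5)
  tab <- simulate_risk_factors(tab, 2, list(cont_feature("a", 0, 1)), seed = 1)
  expect_error(simulate_response(tab, effect_spec(additive = list(
    b = list(shape = "linear", coef = 1)))), "not present")
  expect_error(simulate_response(tab, effect_spec(additive = list(
    a = list(shape = "threshold_linear", coef = 1, threshold = 9)))),
    "outside")
  expect_error(simulate_response(tab, effect_spec(interactions = list(
    list(a = "a", b = "a", threshold_a = 5, coef = 1)))), "outside")
})

test_that("county tables round-trip through CSV with factor types intact", {
  tab <- small_counties(6, 6, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_county_csv(tab, path)
  back <- read_county_csv(path)
  expect_equal(as.data.frame(back)$response, tab$response)
  expect_true(is.factor(back$radon_zone))
  expect_equal(levels(back$coal), levels(droplevels(tab$coal)))
})
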