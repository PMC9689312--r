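test_that("temperature laws match independent scalar evaluation", {
  pb <- bio_truth()
  pc <- co2_truth()
  # independently coded scalar oracle on a 17-28 C grid
  for (temp in seq(17, 28, by = 0.5)) {
    lb <- temperature_laws("biomass", temp, pb)
    expect_equal(lb$mu_max, 0.400 * log(temp) - 1.1, tolerance = 1e-12)
    expect_equal(lb$r_vdk, 0.025 * log(temp) - 0.056, tolerance = 1e-12)
    lc <- temperature_laws("co2", temp, pc)
    expect_equal(lc$mu_max, 1.41 * log(temp) - 3.89, tolerance = 1e-12)
    expect_equal(lc$r_vdk, -3e-4 * temp^2 + 1.6e-2 * temp - 0.175,
                 tolerance = 1e-12)
  }
  # frozen spot values at 19 C
  expect_equal(temperature_laws("biomass", 19, pb)$mu_max, 0.0777756,
               tolerance = 1e-5)
  expect_equal(temperature_laws("co2", 19, pc)$r_vdk, 0.0207,
               tolerance = 1e-10)
})

test_that("temperature laws handle constants, domain errors and extrapolation", {
  pb <- bio_truth()
  const <- c(pb[c("kS", "kE", "Smin", "deltaX", "kV", "kCO2")],
             mu_max = 0.2, r_vdk = 0.01)
  for (temp in c(5, 19, 40))
    expect_equal(temperature_laws("biomass", temp, const)$mu_max, 0.2)
  expect_error(temperature_laws("biomass", 0, pb), "positive")
  expect_error(temperature_laws("biomass", -3, pb), "positive")
  expect_warning(temperature_laws("biomass", 2, pb), "extrapolated")
})

test_that("Droop growth law is continuous, thresholded and monotone", {
  expect_identical(mu_biomass(13.1, 0.2, 13.1), 0)
  expect_equal(mu_biomass(2 * 13.1, 0.2, 13.1), 0.1)
  expect_identical(mu_biomass(0.5 * 13.1, 0.2, 13.1), 0)
  expect_identical(mu_biomass(0, 0.2, 13.1), 0)
  # continuity at the threshold
  expect_lt(mu_biomass(13.1 + 1e-9, 0.2, 13.1), 1e-10)
  # non-decreasing in S
  s <- seq(0, 100, by = 0.5)
  expect_true(all(diff(mu_biomass(s, 0.2, 13.1)) >= 0))
})

test_that("Monod-logistic rate has the right fixed points and monotonicity", {
  p <- co2_truth()
  cap <- p[["Cpmax"]] * 72
  expect_equal(mu_co2(40, cap, 0.26, p[["KS"]], p[["Cpmax"]], 72), 0)
  expect_equal(mu_co2(p[["KS"]], 0, 0.26, p[["KS"]], p[["Cpmax"]], 72),
               0.26 / 2)
  # mid-fermentation value forced by the default parameters at 19 C
  mu_max <- temperature_laws("co2", 19, p)$mu_max
  S <- 72 - p[["kS"]] * 78.48
  expect_equal(mu_co2(S, 78.48, mu_max, p[["KS"]], p[["Cpmax"]], 72),
               0.1022, tolerance = 1e-3)
  expect_warning(mu_co2(40, cap * 1.01, 0.26, p[["KS"]], p[["Cpmax"]], 72),
                 "carrying capacity")
  # non-decreasing in S, non-increasing in CO2
  expect_true(all(diff(mu_co2(seq(1, 70, 1), 10, 0.26, 12, 2.18, 72)) >= 0))
  expect_true(all(diff(mu_co2(40, seq(0, 150, 5), 0.26, 12, 2.18, 72)) <= 0))
})

test_that("biomass RHS respects stoichiometry and degenerate states", {
  p <- bio_truth()
  st <- c(X = 2, S = 40, E = 10, CO2 = 30, VDK = 0.4)
  dx <- biomass_rhs(st, p, 19)
  # ethanol and sugar rates share the factor mu_X * X
  expect_equal(dx[["E"]] * p[["kS"]], -dx[["S"]] * p[["kE"]],
               tolerance = 1e-12)
  expect_gt(dx[["CO2"]], 0)  # CO2 is a product
  # below the sugar threshold only settling and VDK reduction remain
  st_low <- c(X = 2, S = 10, E = 10, CO2 = 30, VDK = 0.4)
  dl <- biomass_rhs(st_low, p, 19)
  expect_equal(dl[["S"]], 0)
  expect_equal(dl[["E"]], 0)
  expect_equal(dl[["CO2"]], 0)
  expect_equal(dl[["X"]], -p[["deltaX"]] * 2)
  # no biomass: only VDK reduction is active
  st0 <- c(X = 0, S = 40, E = 10, CO2 = 30, VDK = 0.4)
  d0 <- biomass_rhs(st0, p, 19)
  r_vdk <- temperature_laws("biomass", 19, p)$r_vdk
  expect_equal(unname(d0), c(0, 0, 0, 0, -r_vdk * 0.4))
})

test_that("CO2 RHS has the logistic fixed point and algebraic outputs", {
  p <- co2_truth()
  z <- co2_rhs(c(CO2 = 0, VDK = 0), p, 19, S0 = 72)
  expect_equal(z$deriv[["CO2"]], 0)  # fermentation never starts from 0
  mid <- co2_rhs(c(CO2 = 78.48, VDK = 0.2), p, 19, S0 = 72)
  expect_equal(mid$deriv[["CO2"]], 8.02, tolerance = 2e-3)
  for (co2 in c(0, 10, 100))
    expect_equal(co2_rhs(c(CO2 = co2, VDK = 0), p, 19, S0 = 72)$outputs[["S"]],
                 72 - 0.372 * co2, tolerance = 1e-12)
})
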