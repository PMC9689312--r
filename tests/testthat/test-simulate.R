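test_that("no-biomass batch follows the closed form", {
  p <- bio_truth()
  d0 <- experiment_design("nb", duration = 40, temperature = 19,
                          S0 = 50, X0 = 0, VDK0 = 1.2)
  tr <- integrate_model("biomass", p, d0, t_grid = seq(0, 40, 5))
  r_vdk <- temperature_laws("biomass", 19, p)$r_vdk
  expect_equal(tr$S, rep(50, 9), tolerance = 1e-10)
  expect_equal(tr$E, rep(0, 9), tolerance = 1e-10)
  expect_equal(tr$CO2, rep(0, 9), tolerance = 1e-10)
  expect_equal(tr$VDK, 1.2 * exp(-r_vdk * tr$time_h), tolerance = 1e-6)
})

test_that("trajectories satisfy monotonicity and threshold invariants", {
  for (model_id in c("biomass", "co2")) {
    p <- default_params(model_id)
    tr <- integrate_model(model_id, p, default_designs()[["2"]])
    expect_true(all(diff(tr$S) <= 1e-9))
    expect_true(all(diff(tr$E) >= -1e-9))
    expect_true(all(diff(tr$CO2) >= -1e-9))
  }
  pb <- bio_truth()
  trb <- integrate_model("biomass", pb, default_designs()[["2"]])
  expect_true(all(trb$S >= pb[["Smin"]] - 1e-6))
  pc <- co2_truth()
  trc <- integrate_model("co2", pc, default_designs()[["2"]])
  expect_true(all(trc$CO2 <= pc[["Cpmax"]] * 72 + 1e-6))
})

test_that("biomass model conserves its linear first integrals", {
  p <- bio_truth()
  for (id in c("2", "4")) {
    d <- default_designs()[[id]]
    tr <- integrate_model("biomass", p, d, rtol = 1e-10, atol = 1e-12)
    q_s <- (d$S0 - tr$S) / p[["kS"]]
    q_e <- (tr$E - d$E0) / p[["kE"]]
    q_c <- tr$CO2 / p[["kCO2"]]
    expect_lt(max(abs(q_s - q_e)), 1e-6)
    expect_lt(max(abs(q_s - q_c)), 1e-6)
  }
})

test_that("tightening tolerances changes the solution within bounds", {
  p <- co2_truth()
  d <- default_designs()[["2"]]
  coarse <- integrate_model("co2", p, d, rtol = 1e-6, atol = 1e-8)
  fine <- integrate_model("co2", p, d, rtol = 1e-8, atol = 1e-10)
  expect_lt(max(abs(as.matrix(coarse[-1]) - as.matrix(fine[-1]))), 10 * 1e-4)
})

test_that("CO2-model residual sugar converges to its analytic asymptote", {
  p <- co2_truth()
  d <- default_designs()[["2"]]
  d$duration <- 500
  tr <- integrate_model("co2", p, d, t_grid = c(0, 250, 500))
  s_inf <- 72 * (1 - p[["kS"]] * p[["Cpmax"]])
  expect_equal(tr$S[3], s_inf, tolerance = 1e-4)
})

test_that("observe returns exact grid values, interpolants and errors", {
  p <- co2_truth()
  d <- default_designs()[["2"]]
  grid <- seq(0, 54, 2)
  tr <- integrate_model("co2", p, d, t_grid = grid)
  sub <- observe(tr, c("CO2", "S"), c(0, 10, 54))
  expect_identical(sub$CO2, tr$CO2[match(c(0, 10, 54), grid)])
  # CO2-model sugar output is the algebraic map of CO2
  expect_equal(sub$S, 72 - p[["kS"]] * sub$CO2, tolerance = 1e-12)
  # off-grid interpolation close to a direct integration
  direct <- integrate_model("co2", p, d, t_grid = c(0, 11, 54))
  interp <- observe(tr, "CO2", 11)
  expect_equal(interp$CO2, direct$CO2[2], tolerance = 1e-4)
  # degenerate and invalid requests
  empty <- observe(tr, character(), c(0, 10))
  expect_identical(names(empty), "time_h")
  expect_error(observe(tr, "pH", 10), "unknown variable")
  expect_error(observe(tr, "CO2", 55), "outside")
})

test_that("integration rejects bad grids and designs warn out of range", {
  p <- bio_truth()
  d <- default_designs()[["2"]]
  expect_error(integrate_model("biomass", p, d, t_grid = c(0, 60)),
               "within")
  expect_error(integrate_model("biomass", p, d, t_grid = c(10, 5)),
               "increasing")
  expect_warning(experiment_design("w", 72, 31, 80, 0.7), "range")
})

test_that("trajectory export uses the controlled column names", {
  p <- bio_truth()
  tr <- integrate_model("biomass", p, default_designs()[["2"]],
                        t_grid = c(0, 25, 54))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  df <- read.csv(f)
  expect_identical(names(df),
                   c("time_h", "X_gL", "S_gL", "E_gL", "CO2_L", "VDK_ppm"))
  expect_equal(df$S_gL, tr$S, tolerance = 1e-15)
})
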