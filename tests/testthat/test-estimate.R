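test_that("weight matrix squares the per-variable measurement maxima", {
  d <- default_designs()[["2"]]
  ds <- manual_dataset("co2", d,
                       data.frame(time_h = c(0, 5, 10),
                                  CO2 = c(0.5, 1, 2),
                                  VDK = c(3, 10, 7)),
                       c("CO2", "VDK"))
  W <- weight_matrix(ds)
  expect_equal(diag(W), c(CO2 = 4, VDK = 100))
  expect_equal(W[1, 2], 0)
  single <- manual_dataset("co2", d,
                           data.frame(time_h = 0, CO2 = 1), "CO2")
  expect_equal(unname(weight_matrix(single)), matrix(1))
  degenerate <- manual_dataset("co2", d,
                               data.frame(time_h = c(0, 1),
                                          CO2 = c(0, 0), VDK = c(1, 2)),
                               c("CO2", "VDK"))
  expect_error(weight_matrix(degenerate), "degenerate")
})

test_that("objective evaluates the weighted residual quadratic form", {
  # prediction at t = 0 equals the initial condition exactly, so a
  # single-sample dataset gives a hand-computable J
  d <- default_designs()[["2"]]
  d$CO2_0 <- 1
  ds <- manual_dataset("co2", d, data.frame(time_h = 0, CO2 = 2), "CO2")
  spec <- param_spec("co2", free = "kS", init = co2_truth())
  expect_equal(wls_objective(co2_truth()[["kS"]], ds, spec), 0.25,
               tolerance = 1e-10)
  # theta = generating truth on noise-free data gives J ~ 0
  p <- co2_truth()
  train <- coarse_training("co2")
  spec_all <- param_spec("co2", free = names(p), init = p)
  expect_lt(wls_objective(as.numeric(p), train, spec_all), 1e-12)
})

test_that("objective agrees with a scalar-loop oracle and is quadratic", {
  p <- co2_truth()
  d <- default_designs()[["2"]]
  ds <- make_dataset("co2", p, d, variables = c("CO2", "E"),
                     sigma_rel = 0.1, seed = 21,
                     times = c(0, 6, 12))
  spec <- param_spec("co2", free = names(p), init = p)
  J <- wls_objective(as.numeric(p), ds, spec)
  # independent scalar-loop accumulation of the weighted least squares sum
  tr <- integrate_model("co2", p, d, t_grid = ds$times)
  pred <- observe(tr, c("CO2", "E"), ds$times)
  maxima <- c(max(ds$data$CO2), max(ds$data$E))
  J_oracle <- 0
  for (i in seq_along(ds$times))
    for (j in 1:2) {
      v <- c("CO2", "E")[j]
      J_oracle <- J_oracle + (ds$data[[v]][i] - pred[[v]][i])^2 / maxima[j]^2
    }
  expect_equal(J, J_oracle, tolerance = 1e-12)
  # doubling every residual (same weights) quadruples J
  W_list <- list(weight_matrix(ds))
  r1 <- brewkin:::.wls_residuals(as.numeric(p), list(ds), spec, W_list)
  ds2 <- ds
  for (v in c("CO2", "E")) ds2$data[[v]] <- 2 * ds$data[[v]] - pred[[v]]
  r2 <- brewkin:::.wls_residuals(as.numeric(p), list(ds2), spec, W_list)
  expect_equal(sum(r2^2), 4 * sum(r1^2), tolerance = 1e-10)
})

test_that("objective is invariant under experiment reordering", {
  p <- co2_truth()
  train <- coarse_training("co2", sigma_rel = 0.05, seed = 31)
  spec <- param_spec("co2", free = names(p), init = p)
  expect_identical(wls_objective(as.numeric(p), train, spec),
                   wls_objective(as.numeric(p), rev(train), spec))
})

test_that("multi-start fit recovers generating parameters and is deterministic", {
  p <- co2_truth()
  d <- default_designs()[["2"]]
  ds <- make_dataset("co2", p, d, sigma_rel = 0,
                     times = sampling_schedule(54, dt_early = 6))
  init <- p
  init[c("kS", "kE")] <- init[c("kS", "kE")] * 1.3
  spec <- param_spec("co2", free = c("kS", "kE"), init = init)
  fit1 <- multi_start_fit(ds, spec, n_starts = 3, seed = 7, nm_maxit = 200)
  expect_rel(fit1$params[["kS"]], p[["kS"]], 0.01)
  expect_rel(fit1$params[["kE"]], p[["kE"]], 0.01)
  expect_lt(fit1$J_star, 1e-10)
  # J* never exceeds any local minimum in the trace
  expect_true(all(fit1$J_star <= fit1$trace$J_nm + 1e-12))
  fit2 <- multi_start_fit(ds, spec, n_starts = 3, seed = 7, nm_maxit = 200)
  expect_identical(fit1$theta_hat, fit2$theta_hat)
})

test_that("a start at the truth is a fixed point of the fit", {
  p <- co2_truth()
  ds <- make_dataset("co2", p, default_designs()[["2"]], sigma_rel = 0,
                     times = sampling_schedule(54, dt_early = 6))
  spec <- param_spec("co2", free = c("kS", "kE"), init = p)
  fit <- multi_start_fit(ds, spec, n_starts = 1, nm_maxit = 300)
  expect_rel(fit$params[["kS"]], p[["kS"]], 1e-4)
  expect_lt(fit$J_star, 1e-14)
})

test_that("initial-condition re-estimation recovers the generating design", {
  p <- co2_truth()
  d1 <- default_designs()[["1"]]
  ds <- make_dataset("co2", p, d1, sigma_rel = 0)
  fit <- fit_initial_conditions(ds, p, nm_maxit = 200)
  expect_rel(fit$theta_hat[["S0"]], 88, 0.01)
  expect_equal(fit$theta_hat[["CO2_0"]], 0.1, tolerance = 1e-2)
  expect_false(fit$underdetermined)
  # single observation of one variable cannot pin four initial conditions
  tiny <- manual_dataset("co2", d1, data.frame(time_h = 0, CO2 = 0.1), "CO2")
  expect_warning(fit_initial_conditions(tiny, p, nm_maxit = 10),
                 "underdetermined")
})

test_that("single-temperature data degrades the staged fit gracefully", {
  p <- bio_truth()
  designs <- default_designs()[c("1", "2")]  # both at 19 C
  ds <- lapply(designs, function(d)
    make_dataset("biomass", p, d, sigma_rel = 0,
                 times = sampling_schedule(d$duration, dt_early = 9,
                                           dt_late = 20)))
  expect_warning(
    fit <- staged_fit_biomass(ds, init = p, n_starts = 1, nm_maxit = 60),
    "unidentifiable")
  expect_false(fit$temperature_identifiable)
  expect_named(fit$stages, "a")
  expect_true(all(c("mu_max", "r_vdk") %in% names(fit$theta_hat)))
})
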