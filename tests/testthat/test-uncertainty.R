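test_that("a-posteriori error estimate divides J by the residual dof", {
  expect_equal(epsilon_hat2(2, 5, 5, 5), 0.1)
  expect_equal(epsilon_hat2(0, 10, 2, 3), 0)
  expect_error(epsilon_hat2(1, 1, 5, 5), "exceed")
})

test_that("FIM and covariance satisfy the identity and additivity cases", {
  # identity sensitivities at one sample, unit noise: FIM = Sigma = I
  sens <- array(diag(2), dim = c(1, 2, 2),
                dimnames = list(NULL, c("y1", "y2"), c("p1", "p2")))
  W <- diag(2)
  fc <- fim_and_covariance(sens, W, eps2 = 1)
  expect_equal(fc$FIM, diag(2), ignore_attr = TRUE)
  expect_equal(fc$Sigma, diag(2), ignore_attr = TRUE)
  expect_false(fc$pseudo_inverse)
  # duplicating every sample doubles the information, halves the covariance
  sens2 <- array(NA_real_, dim = c(2, 2, 2), dimnames = dimnames(sens))
  sens2[1, , ] <- diag(2)
  sens2[2, , ] <- diag(2)
  fc2 <- fim_and_covariance(sens2, W, eps2 = 1)
  expect_equal(fc2$FIM, 2 * diag(2), ignore_attr = TRUE)
  expect_equal(fc2$Sigma, diag(2) / 2, ignore_attr = TRUE)
  # FIM symmetric positive semi-definite
  expect_equal(fc2$FIM, t(fc2$FIM))
  expect_true(all(eigen(fc2$FIM)$values >= -1e-8 * sum(diag(fc2$FIM))))
})

test_that("a structurally confounded parameter pair yields a singular FIM", {
  # toy model y = a*b*t: sensitivities [b*t, a*t] are proportional
  a <- 2; b <- 3; t <- 1:3
  sens <- array(NA_real_, dim = c(3, 1, 2),
                dimnames = list(NULL, "y", c("a", "b")))
  sens[, 1, "a"] <- b * t
  sens[, 1, "b"] <- a * t
  expect_warning(fc <- fim_and_covariance(sens, matrix(1), eps2 = 0.5),
                 "ill-conditioned")
  expect_true(fc$pseudo_inverse)
  expect_gt(fc$cond, 1e10)
})

test_that("coefficients of variation and error bars follow their formulas", {
  Sigma <- diag(c(0.25, 0))
  cv <- coefficients_of_variation(Sigma, c(th1 = 10, th2 = 3))
  expect_equal(cv, c(th1 = 5, th2 = 0))
  expect_true(is.na(coefficients_of_variation(Sigma, c(a = 0, b = 1))[["a"]]))
  W <- matrix(4, 1, 1, dimnames = list("x", "x"))
  expect_equal(unname(error_bars(W, 0.01)), 0.392)
  expect_equal(unname(error_bars(W, 0)), 0)
  # scaling a variable's data by 10 scales its half-width by 10
  ds <- manual_dataset("co2", default_designs()[["2"]],
                       data.frame(time_h = c(0, 1), CO2 = c(1, 2)), "CO2")
  ds10 <- ds
  ds10$data$CO2 <- 10 * ds$data$CO2
  expect_equal(error_bars(weight_matrix(ds10), 0.01),
               10 * error_bars(weight_matrix(ds), 0.01))
})

test_that("finite-difference sensitivities match structure and closed forms", {
  pb <- bio_truth()
  d2 <- default_designs()[["2"]]
  ms <- make_dataset("biomass", pb, d2, sigma_rel = 0,
                     times = sampling_schedule(54, dt_early = 6))
  # ethanol is linear in kE given the growth history: dE/dkE = (E - E0)/kE
  spec_ke <- param_spec("biomass", free = "kE", init = pb)
  s <- sensitivities(pb["kE"], list(ms), spec_ke)
  expect_equal(s[[1]][, "E", 1], (ms$data$E - d2$E0) / pb[["kE"]],
               tolerance = 1e-6)
  # kV does not influence sugar: structural zero column
  spec_kv <- param_spec("biomass", free = "kV", init = pb)
  s_kv <- sensitivities(pb["kV"], list(ms), spec_kv)
  expect_lt(max(abs(s_kv[[1]][, "S", 1])), 1e-6)
  # halving the step barely changes the derivative (difference convergence)
  s_half <- sensitivities(pb["kE"], list(ms), spec_ke, rel_step = 5e-6)
  denom <- max(abs(s[[1]][, "E", 1]))
  expect_lt(max(abs(s[[1]][, "E", 1] - s_half[[1]][, "E", 1])) / denom, 1e-4)
})

test_that("noise-free fits report vanishing error and CVs", {
  p <- co2_truth()
  ds <- make_dataset("co2", p, default_designs()[["2"]], sigma_rel = 0,
                     times = sampling_schedule(54, dt_early = 6))
  spec <- param_spec("co2", free = c("kS", "kE", "Cpmax"), init = p)
  fit <- multi_start_fit(ds, spec, n_starts = 1, nm_maxit = 200)
  rep <- uncertainty_report(fit, ds)
  expect_lt(rep$eps2, 1e-12)
  expect_true(all(rep$cv < 1e-4))
  expect_true(all(unlist(rep$error_bars) < 1e-3))
})
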