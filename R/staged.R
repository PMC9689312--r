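# Staged identification recipes.
#
# Fitting the temperature-law coefficients directly from a cold start is
# poorly conditioned, so both models are identified in stages: first with
# temperature-independent rates (constant mu_max, r_VDK), then the law
# coefficients with everything else frozen, then a global re-estimation of
# all parameters. Each stage is a multi-start WLS fit.

.distinct_temps <- function(datasets) {
  length(unique(vapply(datasets, function(d) d$design$temperature, 0)))
}

# Constant-rate starting values: temperature laws evaluated at the mean
# batch temperature of the training set.
.const_rate_init <- function(model_id, init, datasets) {
  temps <- vapply(datasets, function(d) d$design$temperature, 0)
  laws <- suppressWarnings(temperature_laws(model_id, mean(temps), init))
  c(mu_max = laws$mu_max, r_vdk = laws$r_vdk)
}

#' Three-stage identification of the biomass model
#'
#' Stage (a): all stoichiometric/kinetic parameters plus constant
#' (temperature-independent) `mu_max` and `r_vdk` are estimated. Stage (b):
#' the four temperature-law coefficients `a, b, c, d` are estimated with
#' the other parameters fixed at their stage-(a) values. Stage (c): global
#' re-estimation of all ten parameters from the previous estimates.
#'
#' Stages (b)-(c) require datasets at two or more distinct temperatures;
#' with a single temperature the temperature laws are unidentifiable, a
#' warning is issued, and the stage-(a) constant-rate fit is returned with
#' flag `temperature_identifiable = FALSE`.
#'
#' @param datasets List of `measurement_set`s (typically designs 2-4).
#' @param init Full named starting vector (ten biomass-model parameters);
#'   default [default_params("biomass")].
#' @param seed Seed for the multi-start draws.
#' @param n_starts Simplex starts per stage (default 1: start from `init`;
#'   increase for a global search).
#' @param nm_maxit Nelder-Mead iteration cap per start.
#' @return The final `fit_result`, with the per-stage history in
#'   `$stages` and `$temperature_identifiable`.
#' @export
staged_fit_biomass <- function(datasets, init = default_params("biomass"),
                               seed = NULL, n_starts = 1, nm_maxit = 500) {
  datasets <- .as_dataset_list(datasets)
  init <- stats::setNames(as.numeric(init), names(init))
  stoich <- c("kS", "kE", "Smin", "deltaX", "kV", "kCO2")
  law <- c("a", "b", "c", "d")

  # (a) no explicit temperature dependence
  init_a <- c(init[stoich], .const_rate_init("biomass", init, datasets))
  spec_a <- param_spec("biomass", free = names(init_a), init = init_a)
  fit_a <- multi_start_fit(datasets, spec_a, n_starts = n_starts,
                           seed = seed, nm_maxit = nm_maxit)

  if (.distinct_temps(datasets) < 2) {
    warning("all datasets share one temperature: temperature-law ",
            "coefficients are unidentifiable; returning the constant-rate ",
            "fit from stage (a)", call. = FALSE)
    fit_a$stages <- list(a = fit_a)
    fit_a$temperature_identifiable <- FALSE
    return(fit_a)
  }

  # (b) temperature-law coefficients only, others fixed from (a)
  init_b <- c(fit_a$params[stoich], init[law])
  spec_b <- param_spec("biomass", free = law, init = init_b)
  fit_b <- multi_start_fit(datasets, spec_b, n_starts = n_starts,
                           seed = seed, nm_maxit = nm_maxit)

  # (c) global re-estimation of all parameters
  init_c <- fit_b$params[c(stoich, law)]
  spec_c <- param_spec("biomass", free = c(stoich, law), init = init_c)
  fit_c <- multi_start_fit(datasets, spec_c, n_starts = n_starts,
                           seed = seed, nm_maxit = nm_maxit)

  fit_c$stages <- list(a = fit_a, b = fit_b, c = fit_c)
  fit_c$temperature_identifiable <- TRUE
  fit_c
}

#' Four-stage identification of the CO2 model
#'
#' Stage (a): stoichiometric/kinetic parameters with constant rates and
#' `KS` frozen at an arbitrary value (`KS_init`; the half-saturation
#' constant has poor practical identifiability). Stage (b): `KS` alone,
#' everything else fixed. Stage (c): the five temperature-law coefficients
#' `a, ..., e`. Stage (d): global re-estimation of all ten parameters.
#'
#' @inheritParams staged_fit_biomass
#' @param init Full named starting vector (ten CO2-model parameters);
#'   default [default_params("co2")].
#' @param KS_init Arbitrary `KS` value used in stage (a) (g/L, default 10).
#' @return The final `fit_result` with `$stages` (a-d) and
#'   `$temperature_identifiable`.
#' @export
staged_fit_co2 <- function(datasets, init = default_params("co2"),
                           KS_init = 10, seed = NULL, n_starts = 1,
                           nm_maxit = 500) {
  datasets <- .as_dataset_list(datasets)
  stopifnot(KS_init > 0)
  init <- stats::setNames(as.numeric(init), names(init))
  stoich <- c("kS", "kE", "Cpmax", "kV")
  law <- c("a", "b", "c", "d", "e")

  # (a) constant rates, KS frozen at an arbitrary value
  init_a <- c(init[stoich], KS = KS_init,
              .const_rate_init("co2", init, datasets))
  spec_a <- param_spec("co2", free = c(stoich, "mu_max", "r_vdk"),
                       init = init_a)
  fit_a <- multi_start_fit(datasets, spec_a, n_starts = n_starts,
                           seed = seed, nm_maxit = nm_maxit)

  # (b) KS alone, everything else fixed from (a)
  init_b <- fit_a$params
  init_b["KS"] <- KS_init
  spec_b <- param_spec("co2", free = "KS", init = init_b)
  fit_b <- multi_start_fit(datasets, spec_b, n_starts = n_starts,
                           seed = seed, nm_maxit = nm_maxit)

  if (.distinct_temps(datasets) < 2) {
    warning("all datasets share one temperature: temperature-law ",
            "coefficients are unidentifiable; returning the constant-rate ",
            "fit from stage (b)", call. = FALSE)
    fit_b$stages <- list(a = fit_a, b = fit_b)
    fit_b$temperature_identifiable <- FALSE
    return(fit_b)
  }

  # (c) temperature-law coefficients, others fixed from (b)
  init_c <- c(fit_b$params[c(stoich, "KS")], init[law])
  spec_c <- param_spec("co2", free = law, init = init_c)
  fit_c <- multi_start_fit(datasets, spec_c, n_starts = n_starts,
                           seed = seed, nm_maxit = nm_maxit)

  # (d) global re-estimation of all parameters
  init_d <- fit_c$params[c(stoich, "KS", law)]
  spec_d <- param_spec("co2", free = names(init_d), init = init_d)
  fit_d <- multi_start_fit(datasets, spec_d, n_starts = n_starts,
                           seed = seed, nm_maxit = nm_maxit)

  fit_d$stages <- list(a = fit_a, b = fit_b, c = fit_c, d = fit_d)
  fit_d$temperature_identifiable <- TRUE
  fit_d
}

#' Re-estimate only the initial conditions of one experiment
#'
#' Cross-validation protocol: the model parameters are kept fixed and only
#' the initial state of a single held-out experiment is estimated (initial
#' conditions are themselves corrupted by measurement noise). Free initial
#' conditions default to the full initial state of the model (`X0, S0, E0,
#' CO2_0, VDK0` for the biomass model; `CO2_0, S0, E0, VDK0` for the CO2
#' model, where `S0` and `E0` enter the algebraic outputs and the carrying
#' capacity).
#'
#' @param dataset A single `measurement_set`.
#' @param fixed_params Complete model parameter vector (kept fixed).
#' @param free_ic Initial-condition names to estimate.
#' @param seed,n_starts,nm_maxit As in [multi_start_fit()].
#' @return A `fit_result` whose free parameters are initial conditions.
#' @export
fit_initial_conditions <- function(dataset, fixed_params,
                                   free_ic = NULL, seed = NULL,
                                   n_starts = 1, nm_maxit = 500) {
  stopifnot(inherits(dataset, "measurement_set"))
  model_id <- dataset$model_id
  if (is.null(free_ic))
    free_ic <- if (model_id == "biomass") {
      c("X0", "S0", "E0", "CO2_0", "VDK0")
    } else {
      c("CO2_0", "S0", "E0", "VDK0")
    }
  stopifnot(all(free_ic %in% .IC_NAMES))
  des <- dataset$design
  ic_init <- stats::setNames(vapply(free_ic, function(k) {
    v <- des[[k]]
    if (is.na(v)) v <- if (model_id == "co2") 0.1 else 0
    v
  }, 0), free_ic)

  # Bounds: a decade either side for positive initial values; [0, scale]
  # for zero ones, scaled by the largest observation of the matching
  # variable (or the initial sugar as a generic magnitude).
  lo <- hi <- ic_init
  for (k in free_ic) {
    v <- ic_init[[k]]
    if (v > 0) {
      lo[k] <- v / 10; hi[k] <- v * 10
    } else {
      var <- sub("_?0$", "", k)
      obs_max <- if (var %in% dataset$variables)
        max(dataset$data[[var]], na.rm = TRUE) else NA_real_
      lo[k] <- 0
      hi[k] <- max(1, if (is.finite(obs_max)) 2 * obs_max else 0.5 * des$S0)
    }
  }
  full_init <- c(stats::setNames(as.numeric(fixed_params),
                                 names(fixed_params)), ic_init)
  spec <- param_spec(model_id, free = free_ic, init = full_init,
                     lower = lo, upper = hi)
  n_scalar_obs <- sum(!is.na(as.matrix(dataset$data[dataset$variables])))
  fit <- multi_start_fit(dataset, spec, n_starts = n_starts, seed = seed,
                         nm_maxit = nm_maxit)
  if (n_scalar_obs < length(free_ic)) {
    warning("fewer observations than free initial conditions: ",
            "underdetermined estimate", call. = FALSE)
    fit$underdetermined <- TRUE
  } else {
    fit$underdetermined <- FALSE
  }
  fit
}
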