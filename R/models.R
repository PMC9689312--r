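# Kinetic rate laws and ODE right-hand sides of the two fermentation models.
#
# Biomass model (states X, S, E, CO2, VDK):
#   dX/dt   = (mu_X - deltaX) X
#   dS/dt   = -kS   mu_X X
#   dE/dt   = +kE   mu_X X
#   dCO2/dt = +kCO2 mu_X X
#   dVDK/dt = kV mu_X X - r_VDK VDK
#   mu_X = mu_max * max(0, 1 - Smin/S)          (Droop-type threshold law)
#
# CO2 model (dynamic states CO2, VDK; S and E algebraic):
#   dCO2/dt = mu_X CO2
#   dVDK/dt = kV mu_X CO2 - r_VDK VDK
#   S = S0 - kS CO2,  E = E0 + kE CO2
#   mu_X = mu_max * S/(KS + S) * (1 - CO2/(Cpmax S0))   (Monod x logistic)
#
# Temperature enters through mu_max and r_VDK only; each batch is isothermal.

#' Temperature laws for the maximum growth rate and VDK reduction rate
#'
#' The biomass model uses `mu_max = a*ln(T) + b` and `r_VDK = c*ln(T) + d`;
#' the CO2 model uses `mu_max = a*ln(T) + b` and `r_VDK = c*T^2 + d*T + e`.
#' Temperature is in degrees Celsius; the laws are calibrated over 17-28 C
#' and a warning is issued when an evaluated rate is negative (the model is
#' being extrapolated outside its supported range).
#'
#' A parameter vector containing entries `mu_max` and `r_vdk` short-circuits
#' the laws and returns those constants; the early stages of the staged fits
#' use this to estimate temperature-independent rates.
#'
#' @param model_id `"biomass"` or `"co2"`.
#' @param temp Temperature(s) in degrees Celsius; must be strictly positive.
#' @param params Parameter vector (see [ferm_params()]).
#' @return A list with numeric components `mu_max` and `r_vdk` (1/h).
#' @export
#' @examples
#' temperature_laws("biomass", 19, default_params("biomass"))
temperature_laws <- function(model_id, temp, params) {
  model_id <- .check_model_id(model_id)
  if (any(!is.finite(temp)) || any(temp <= 0))
    stop("temperature must be strictly positive (degrees Celsius)")
  p <- as.list(params)
  if (!is.null(p$mu_max) && !is.null(p$r_vdk)) {
    mu_max <- rep_len(p$mu_max, length(temp))
    r_vdk <- rep_len(p$r_vdk, length(temp))
  } else {
    mu_max <- p$a * log(temp) + p$b
    r_vdk <- if (model_id == "biomass") {
      p$c * log(temp) + p$d
    } else {
      p$c * temp^2 + p$d * temp + p$e
    }
  }
  if (any(mu_max < 0) || any(r_vdk < 0))
    warning("negative rate from temperature law: model extrapolated ",
            "outside its calibrated 17-28 C range", call. = FALSE)
  list(mu_max = mu_max, r_vdk = r_vdk)
}

#' Droop-type specific growth rate of the biomass model
#'
#' `mu_X = mu_max * max(0, 1 - Smin/S)`: growth requires a minimum residual
#' sugar `Smin`; the rate is continuous and vanishes for `S <= Smin`.
#'
#' @param S Sugar concentration (g/L), `>= 0`.
#' @param mu_max Maximum specific growth rate (1/h).
#' @param Smin Residual sugar threshold (g/L), `> 0`.
#' @return Specific growth rate (1/h), vectorized over `S`.
#' @export
mu_biomass <- function(S, mu_max, Smin) {
  mu_max * pmax(0, 1 - Smin / pmax(S, .Machine$double.xmin))
}

#' Monod-logistic specific rate of the CO2 model
#'
#' `mu_X = mu_max * S/(KS+S) * (1 - CO2/(Cpmax*S0))`: Monod activation by
#' sugar and a logistic brake that vanishes at the carrying capacity
#' `Cpmax * S0`.
#'
#' @param S Sugar concentration (g/L).
#' @param CO2 Cumulative CO2 volume (L).
#' @param mu_max Maximum specific rate (1/h).
#' @param KS Half-saturation constant (g/L).
#' @param Cpmax Carrying-capacity factor (L CO2 per g initial sugar).
#' @param S0 Initial sugar concentration (g/L), `> 0`.
#' @param warn_overshoot Warn when `CO2` exceeds the carrying capacity
#'   (negative rate); default `TRUE`.
#' @return Specific rate (1/h), vectorized.
#' @export
mu_co2 <- function(S, CO2, mu_max, KS, Cpmax, S0, warn_overshoot = TRUE) {
  cap <- Cpmax * S0
  if (warn_overshoot && any(CO2 > cap))
    warning("CO2 exceeds carrying capacity Cpmax*S0: negative rate",
            call. = FALSE)
  mu_max * S / (KS + S) * (1 - CO2 / cap)
}

#' Right-hand side of the biomass model
#'
#' @param state Named numeric vector with entries `X, S, E, CO2, VDK`.
#' @param params Biomass-model parameter vector.
#' @param temp Batch temperature (degrees Celsius).
#' @return Named vector of time derivatives (same order as `state`).
#' @export
biomass_rhs <- function(state, params, temp) {
  laws <- suppressWarnings(temperature_laws("biomass", temp, params))
  .biomass_rhs(state, as.list(params), laws)
}

.biomass_rhs <- function(state, p, laws) {
  mu <- mu_biomass(state[["S"]], laws$mu_max, p$Smin)
  growth <- mu * state[["X"]]
  c(X = (mu - p$deltaX) * state[["X"]],
    S = -p$kS * growth,
    E = p$kE * growth,
    CO2 = p$kCO2 * growth,
    VDK = p$kV * growth - laws$r_vdk * state[["VDK"]])
}

#' Right-hand side of the CO2 model
#'
#' Returns the derivatives of the two dynamic states and the algebraic
#' sugar and ethanol outputs `S = S0 - kS*CO2`, `E = E0 + kE*CO2`.
#'
#' @param state Named numeric vector with entries `CO2, VDK`.
#' @param params CO2-model parameter vector.
#' @param temp Batch temperature (degrees Celsius).
#' @param S0,E0 Initial sugar and ethanol concentrations (g/L).
#' @return List with components `deriv` (named vector) and `outputs`
#'   (named vector `S`, `E`).
#' @export
co2_rhs <- function(state, params, temp, S0, E0 = 0) {
  laws <- suppressWarnings(temperature_laws("co2", temp, params))
  .co2_rhs(state, as.list(params), laws, S0, E0)
}

.co2_rhs <- function(state, p, laws, S0, E0) {
  S <- S0 - p$kS * state[["CO2"]]
  mu <- mu_co2(S, state[["CO2"]], laws$mu_max, p$KS, p$Cpmax, S0,
               warn_overshoot = FALSE)
  list(deriv = c(CO2 = mu * state[["CO2"]],
                 VDK = p$kV * mu * state[["CO2"]] - laws$r_vdk * state[["VDK"]]),
       outputs = c(S = S, E = E0 + p$kE * state[["CO2"]]))
}

# State/output variable names per model, in canonical column order.
.MODEL_VARS <- list(
  biomass = c("X", "S", "E", "CO2", "VDK"),
  co2     = c("CO2", "S", "E", "VDK")
)

# Dynamic states per model.
.MODEL_STATES <- list(
  biomass = c("X", "S", "E", "CO2", "VDK"),
  co2     = c("CO2", "VDK")
)
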