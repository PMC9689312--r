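# Batch simulation: experiment designs, ODE integration, output observation.

#' Describe one batch experiment
#'
#' An experiment design bundles a batch's operating conditions: duration,
#' (constant) temperature, and initial state. `CO2_0 = NA` selects the
#' model default at integration time: 0 L for the biomass model, 0.1 L for
#' the CO2 model (whose logistic dynamics have a fixed point at exactly 0).
#'
#' @param id Identifier (integer or string).
#' @param duration Batch duration (h), `> 0`.
#' @param temperature Batch temperature (degrees Celsius). Values outside
#'   the calibrated 17-28 C range trigger a warning, not an error.
#' @param S0 Initial sugar concentration (g/L), `> 0`.
#' @param X0 Initial biomass concentration (g/L), `>= 0`.
#' @param E0,VDK0 Initial ethanol (g/L) and VDK (ppm); default 0.
#' @param CO2_0 Initial cumulative CO2 (L); `NA` = model default.
#' @return An object of class `experiment_design`.
#' @export
#' @examples
#' experiment_design(1, duration = 72, temperature = 19, S0 = 88, X0 = 0.705)
experiment_design <- function(id, duration, temperature, S0, X0,
                              E0 = 0, VDK0 = 0, CO2_0 = NA_real_) {
  stopifnot(duration > 0, S0 > 0, X0 >= 0, E0 >= 0, VDK0 >= 0)
  if (is.finite(temperature) && (temperature < 17 || temperature > 28))
    warning("temperature ", temperature,
            " C outside the calibrated 17-28 C range", call. = FALSE)
  structure(list(id = id, duration = duration, temperature = temperature,
                 S0 = S0, X0 = X0, E0 = E0, VDK0 = VDK0, CO2_0 = CO2_0),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("<experiment_design> id=%s  %g h at %g C  S0=%g g/L  X0=%g g/L\n",
              x$id, x$duration, x$temperature, x$S0, x$X0))
  invisible(x)
}

.initial_state <- function(model_id, design) {
  co2_0 <- design$CO2_0
  if (is.na(co2_0)) co2_0 <- if (model_id == "co2") 0.1 else 0
  if (model_id == "biomass") {
    c(X = design$X0, S = design$S0, E = design$E0, CO2 = co2_0,
      VDK = design$VDK0)
  } else {
    c(CO2 = co2_0, VDK = design$VDK0)
  }
}

#' Integrate a fermentation model over a batch
#'
#' Solves the model ODEs with a stiff-capable integrator (`deSolve::ode`,
#' method `"lsoda"`) and returns the trajectory evaluated exactly on the
#' requested time grid. For the CO2 model the algebraic sugar and ethanol
#' outputs are appended as columns. State values are clipped to `>= 0` in
#' the returned table only, never inside the integrator.
#'
#' Defaults `rtol = 1e-8`, `atol = 1e-10` are tight because trajectories
#' feed finite-difference sensitivities downstream.
#'
#' @param model_id `"biomass"` or `"co2"`.
#' @param params Parameter vector for the model.
#' @param design An [experiment_design()].
#' @param t_grid Time grid (h) within `[0, duration]`; default 201 equally
#'   spaced points.
#' @param rtol,atol Integrator tolerances, `> 0`.
#' @return A `ferm_trajectory`: a data frame with column `time_h` and one
#'   column per state/output, plus attributes `model_id`, `design`,
#'   `params`.
#' @export
integrate_model <- function(model_id, params, design, t_grid = NULL,
                            rtol = 1e-8, atol = 1e-10) {
  model_id <- .check_model_id(model_id)
  stopifnot(rtol > 0, atol > 0)
  if (is.null(t_grid))
    t_grid <- seq(0, design$duration, length.out = 201)
  t_grid <- as.numeric(t_grid)
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing")
  if (min(t_grid) < 0 || max(t_grid) > design$duration)
    stop("t_grid must lie within [0, duration]")

  p <- as.list(params)
  laws <- suppressWarnings(
    temperature_laws(model_id, design$temperature, params))
  y0 <- .initial_state(model_id, design)
  times <- if (t_grid[1] > 0) c(0, t_grid) else t_grid

  deriv_fn <- if (model_id == "biomass") {
    function(t, y, parms) list(.biomass_rhs(y, p, laws))
  } else {
    function(t, y, parms) list(.co2_rhs(y, p, laws, design$S0, design$E0)$deriv)
  }

  if (length(times) == 1) {
    # degenerate single-instant grid at t = 0: the state is the initial one
    sol <- as.data.frame(as.list(c(time = times, y0)))
    out <- data.frame(time_h = t_grid)
    if (model_id == "biomass") {
      for (v in .MODEL_VARS$biomass) out[[v]] <- pmax(sol[[v]], 0)
    } else {
      out$CO2 <- pmax(sol$CO2, 0)
      out$S <- pmax(design$S0 - p$kS * out$CO2, 0)
      out$E <- design$E0 + p$kE * out$CO2
      out$VDK <- pmax(sol$VDK, 0)
    }
    return(structure(out, class = c("ferm_trajectory", "data.frame"),
                     model_id = model_id, design = design, params = params))
  }

  sol <- try(deSolve::ode(y = y0, times = times, func = deriv_fn,
                          parms = NULL, method = "lsoda",
                          rtol = rtol, atol = atol), silent = TRUE)
  if (inherits(sol, "try-error"))
    stop("integration failed for design ", design$id, ": ",
         attr(sol, "condition")$message)
  if (nrow(sol) < length(times)) {
    t_fail <- if (nrow(sol) > 0) sol[nrow(sol), 1] else times[1]
    stop("integrator stopped at t = ", signif(t_fail, 6),
         " h (design ", design$id, ")")
  }
  sol <- as.data.frame(sol)
  if (t_grid[1] > 0) sol <- sol[-1, , drop = FALSE]

  out <- data.frame(time_h = t_grid)
  if (model_id == "biomass") {
    for (v in .MODEL_VARS$biomass) out[[v]] <- pmax(sol[[v]], 0)
  } else {
    out$CO2 <- pmax(sol$CO2, 0)
    out$S <- pmax(design$S0 - p$kS * out$CO2, 0)
    out$E <- design$E0 + p$kE * out$CO2
    out$VDK <- pmax(sol$VDK, 0)
  }
  structure(out, class = c("ferm_trajectory", "data.frame"),
            model_id = model_id, design = design, params = params)
}

#' Evaluate a trajectory at arbitrary times
#'
#' Returns noise-free values of the requested variables at the requested
#' times. Times that coincide with the integration grid are returned
#' exactly; times in between are interpolated with a cubic spline (no
#' extrapolation outside the trajectory span).
#'
#' @param traj A `ferm_trajectory` from [integrate_model()].
#' @param variables Character vector of variable names (subset of the
#'   trajectory's columns); an empty vector yields a table with only
#'   `time_h`.
#' @param times Times (h) within the trajectory span.
#' @return Data frame with `time_h` and one column per requested variable.
#' @export
observe <- function(traj, variables, times) {
  stopifnot(inherits(traj, "ferm_trajectory"))
  bad <- setdiff(variables, setdiff(names(traj), "time_h"))
  if (length(bad))
    stop("unknown variable(s) for this model: ", paste(bad, collapse = ", "))
  tr <- traj$time_h
  if (any(times < min(tr)) || any(times > max(tr)))
    stop("requested times outside the trajectory span")
  out <- data.frame(time_h = times)
  idx <- match(round(times, 12), round(tr, 12))
  for (v in variables) {
    vals <- numeric(length(times))
    hit <- !is.na(idx)
    vals[hit] <- traj[[v]][idx[hit]]
    if (any(!hit))
      vals[!hit] <- spline(tr, traj[[v]], xout = times[!hit])$y
    out[[v]] <- vals
  }
  out
}

#' @export
print.ferm_trajectory <- function(x, ...) {
  d <- attr(x, "design")
  cat(sprintf("<ferm_trajectory> %s model, design %s, %d time points on [%g, %g] h\n",
              attr(x, "model_id"), d$id, nrow(x), min(x$time_h), max(x$time_h)))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

#' Export a trajectory as delimited text
#'
#' Writes a CSV with column `time_h` followed by the state/output columns
#' using the controlled vocabulary `X_gL, S_gL, E_gL, CO2_L, VDK_ppm`.
#'
#' @param traj A `ferm_trajectory`.
#' @param path Output file path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "ferm_trajectory"))
  df <- as.data.frame(traj)
  vars <- setdiff(names(df), "time_h")
  names(df) <- c("time_h", unname(.COLUMN_MAP[vars]))
  .write_csv_full(df, path)
  invisible(path)
}

# Full-precision CSV writer shared by the export helpers.
.write_csv_full <- function(df, path) {
  fmt <- df
  for (j in seq_along(fmt))
    if (is.numeric(fmt[[j]]))
      fmt[[j]] <- ifelse(is.na(fmt[[j]]), "", sprintf("%.17g", fmt[[j]]))
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
}
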