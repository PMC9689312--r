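# Synthetic measurement sets emulating the reference batch experiments:
# four isothermal batch designs, a dense-then-sparse sampling schedule, and
# a relative-error Gaussian noise model scaled by each variable's
# trajectory maximum.

#' The four reference batch designs
#'
#' Operating conditions of the four isothermal ale fermentations used
#' throughout the package: duration, temperature, and initial sugar and
#' biomass concentrations. Experiments 2-4 are the conventional training
#' partition; experiment 1 is held out for cross-validation.
#'
#' @return A named list of four [experiment_design()] objects
#'   (`"1"` ... `"4"`).
#' @export
#' @examples
#' default_designs()[["1"]]
default_designs <- function() {
  d <- list(
    experiment_design(1, duration = 72, temperature = 19, S0 = 88, X0 = 0.705),
    experiment_design(2, duration = 54, temperature = 19, S0 = 72, X0 = 0.529),
    experiment_design(3, duration = 96, temperature = 21, S0 = 75, X0 = 0.705),
    experiment_design(4, duration = 72, temperature = 28, S0 = 81, X0 = 0.705)
  )
  stats::setNames(d, vapply(d, function(x) as.character(x$id), ""))
}

#' Batch sampling schedule
#'
#' Samples are dense early in the batch (every `dt_early` hours up to
#' `t_switch`, when the process approaches its stationary phase) and sparse
#' afterwards (every `dt_late` hours). The switch time and the batch end
#' are always included.
#'
#' @param duration Batch duration (h), `> 0`.
#' @param dt_early Early-phase sampling interval (h), default 2.5.
#' @param t_switch Time at which sampling slows down (h), default 36.
#' @param dt_late Late-phase sampling interval (h), default 8.
#' @return Increasing vector of sample times starting at 0 and ending at
#'   `duration`.
#' @export
#' @examples
#' sampling_schedule(54)
sampling_schedule <- function(duration, dt_early = 2.5, t_switch = 36,
                              dt_late = 8) {
  stopifnot(duration > 0, dt_early > 0, dt_late > 0, t_switch > 0)
  times <- seq(0, min(t_switch, duration), by = dt_early)
  if (duration >= t_switch) {
    times <- c(times, t_switch)
    if (t_switch + dt_late <= duration)
      times <- c(times, seq(t_switch + dt_late, duration, by = dt_late))
  }
  times <- sort(unique(c(times, duration)))
  times[times <= duration]
}

#' Generate a (possibly noisy) synthetic measurement set
#'
#' Simulates the chosen model under `design`, samples the requested
#' variables on `times` (default: [sampling_schedule()] for the design's
#' duration), and adds zero-mean Gaussian noise with standard deviation
#' `sigma_rel * max_t(y_true)` per variable -- a relative-error model in
#' which the error scale is proportional to the maximum of each observed
#' variable. Noisy values are truncated at 0 (concentrations cannot be
#' negative); the truncation is recorded in the noise descriptor.
#'
#' @param model_id `"biomass"` or `"co2"`.
#' @param params Parameter vector used as ground truth.
#' @param design An [experiment_design()].
#' @param variables Observed variables; default all model outputs.
#' @param sigma_rel Relative noise level, `>= 0`; `0` gives noise-free data
#'   identical to the simulator output.
#' @param seed Integer seed making the draw reproducible; `NULL` leaves the
#'   RNG state alone.
#' @param times Sample times; default the standard schedule.
#' @return A `measurement_set`: list with elements `model_id`, `design`,
#'   `times`, `data` (data frame `time_h` + one column per variable),
#'   `sigma_rel`, `sigma_abs` (named per-variable noise sd), `seed`,
#'   `truncated_at_zero`, `provenance`.
#' @export
make_dataset <- function(model_id, params, design, variables = NULL,
                         sigma_rel = 0.05, seed = NULL, times = NULL) {
  model_id <- .check_model_id(model_id)
  stopifnot(sigma_rel >= 0)
  if (is.null(variables)) variables <- .MODEL_VARS[[model_id]]
  bad <- setdiff(variables, .MODEL_VARS[[model_id]])
  if (length(bad))
    stop("unknown variable(s) for the ", model_id, " model: ",
         paste(bad, collapse = ", "))
  if (is.null(times)) times <- sampling_schedule(design$duration)

  traj <- integrate_model(model_id, params, design, t_grid = times)
  data <- observe(traj, variables, times)

  sigma_abs <- stats::setNames(rep(0, length(variables)), variables)
  if (sigma_rel > 0) {
    if (!is.null(seed)) set.seed(seed)
    for (v in variables) {
      sd_v <- sigma_rel * max(data[[v]])
      sigma_abs[v] <- sd_v
      data[[v]] <- pmax(0, data[[v]] + rnorm(nrow(data), sd = sd_v))
    }
  }
  structure(list(model_id = model_id, design = design, times = times,
                 data = data, variables = variables, sigma_rel = sigma_rel,
                 sigma_abs = sigma_abs, seed = seed,
                 truncated_at_zero = sigma_rel > 0, provenance = "synthetic"),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf(
    "<measurement_set> %s model, design %s (%s), %d samples, vars: %s, sigma_rel=%g\n",
    x$model_id, x$design$id, x$provenance, length(x$times),
    paste(x$variables, collapse = ","), x$sigma_rel))
  invisible(x)
}

# Internal: noise-free training bundle for designs 2-4 (shared by the
# staged-fit examples, tests and the acceptance script).
.training_datasets <- function(model_id, params = default_params(model_id),
                               sigma_rel = 0, seed = NULL,
                               variables = NULL) {
  designs <- default_designs()[c("2", "3", "4")]
  seeds <- if (is.null(seed)) vector("list", 3) else as.list(seed + 0:2)
  out <- lapply(seq_along(designs), function(i)
    make_dataset(model_id, params, designs[[i]], variables = variables,
                 sigma_rel = sigma_rel, seed = seeds[[i]]))
  stats::setNames(out, names(designs))
}
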