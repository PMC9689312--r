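# Numerical local observability / identifiability rank test.
#
# Local observability is decided by the rank of the stack of gradients of
# the outputs and their Lie derivatives along the vector field. Rather than
# nesting high-order finite differences, the gradients are probed through
# the flow: the matrix O[(t,j), i] = d y_j(t) / d x0_i, assembled over a
# short sequence of times by central differences on the integrator, spans
# (by the Lie-series expansion of the flow) the same row space as the
# Lie-derivative stack at a generic point. Rank deficiency of O identifies
# locally indistinguishable directions; a state is reconstructible exactly
# when its basis direction lies in the row space of O.
#
# Identifiability mode appends the model parameters as constant states
# (zero dynamics) before running the same test. Temperature-law
# coefficients are collapsed to the effective rates mu_max(T), r_vdk(T)
# at the (fixed, known) batch temperature, since only those enter the
# isothermal dynamics.

# Effective (temperature-collapsed) parameter vector used in augmented mode.
.effective_params <- function(model_id, params, temp) {
  laws <- suppressWarnings(temperature_laws(model_id, temp, params))
  p <- as.list(params)
  base <- if (model_id == "biomass") {
    c(kS = p$kS, kE = p$kE, Smin = p$Smin, deltaX = p$deltaX,
      kV = p$kV, kCO2 = p$kCO2)
  } else {
    c(kS = p$kS, kE = p$kE, KS = p$KS, Cpmax = p$Cpmax, kV = p$kV)
  }
  c(base, mu_max = laws$mu_max, r_vdk = laws$r_vdk)
}

# Simulate outputs at `times` from an (optionally augmented) point z.
.obs_outputs <- function(model_id, outputs, z, states, par_names, theta_eff,
                         temp, S0, E0, times, rtol, atol) {
  y0 <- z[states]
  pars <- if (length(par_names)) {
    th <- theta_eff
    th[par_names] <- z[par_names]
    th
  } else theta_eff
  p <- as.list(pars)
  laws <- list(mu_max = pars[["mu_max"]], r_vdk = pars[["r_vdk"]])
  deriv_fn <- if (model_id == "biomass") {
    function(t, y, parms) list(.biomass_rhs(y, p, laws))
  } else {
    function(t, y, parms) list(.co2_rhs(y, p, laws, S0, E0)$deriv)
  }
  sol <- deSolve::ode(y = y0, times = c(0, times), func = deriv_fn,
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (nrow(sol) < length(times) + 1)
    stop("integration failed in observability test")
  sol <- as.data.frame(sol)[-1, , drop = FALSE]
  Y <- matrix(NA_real_, length(times), length(outputs),
              dimnames = list(NULL, outputs))
  for (v in outputs) {
    Y[, v] <- switch(v,
      S = if (model_id == "co2") S0 - p$kS * sol$CO2 else sol$S,
      E = if (model_id == "co2") E0 + p$kE * sol$CO2 else sol$E,
      sol[[v]])
  }
  Y
}

# Observability matrix (log-scaled directions, output-scaled rows) at one
# point; returns the matrix with one column per augmented-state direction.
.obs_matrix <- function(model_id, outputs, point, theta_eff, temp, S0, E0,
                        times, augment, fd_step = 1e-3,
                        rtol = 1e-11, atol = 1e-13) {
  states <- .MODEL_STATES[[model_id]]
  par_names <- if (augment) names(theta_eff) else character()
  z0 <- c(point[states], if (augment) theta_eff)
  stopifnot(all(z0 > 0))
  dim_z <- length(z0)
  Y0 <- .obs_outputs(model_id, outputs, z0, states, par_names, theta_eff,
                     temp, S0, E0, times, rtol, atol)
  yscale <- pmax(apply(abs(Y0), 2, max), 1e-8)
  O <- matrix(NA_real_, length(times) * length(outputs), dim_z,
              dimnames = list(NULL, names(z0)))
  for (j in seq_len(dim_z)) {
    h <- fd_step * z0[j]
    zp <- zm <- z0
    zp[j] <- zp[j] + h
    zm[j] <- zm[j] - h
    Yp <- .obs_outputs(model_id, outputs, zp, states, par_names, theta_eff,
                       temp, S0, E0, times, rtol, atol)
    Ym <- .obs_outputs(model_id, outputs, zm, states, par_names, theta_eff,
                       temp, S0, E0, times, rtol, atol)
    # derivative with respect to the log of z_j, rows scaled per output
    D <- (Yp - Ym) / (2 * h) * z0[j]
    O[, j] <- as.vector(sweep(D, 2, yscale, "/"))
  }
  O
}

.generic_point <- function(model_id, params, S0) {
  p <- as.list(params)
  if (model_id == "biomass") {
    c(X = 2, S = (S0 + p$Smin) / 2, E = 12, CO2 = 25, VDK = 0.5)
  } else {
    c(CO2 = 0.35 * p$Cpmax * S0, VDK = 0.5)
  }
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Local observability / identifiability rank test
#'
#' Decides whether the model state (and, with `augment_params = TRUE`, the
#' model parameters) can be locally reconstructed from the chosen output
#' set, by a numerical rank test of the observability matrix assembled
#' from short-time flow sensitivities (see the package vignette for the
#' method). The test is repeated at `n_points` randomly jittered generic
#' mid-fermentation points; if the verdicts disagree the result is
#' `"indeterminate"`.
#'
#' @param model_id `"biomass"` or `"co2"`.
#' @param outputs Character vector of measured variables (subset of
#'   `X, S, E, CO2, VDK` for the biomass model; `CO2, S, E, VDK` for the
#'   CO2 model).
#' @param params Parameter vector; default the packaged estimates.
#' @param temp Batch temperature (degrees C) at which the test is run.
#' @param S0,E0 Initial sugar/ethanol of the reference batch (the CO2
#'   model's algebraic outputs and carrying capacity depend on them).
#' @param point Optional named state vector at which to test; default:
#'   jittered generic mid-fermentation points (all components strictly
#'   positive, `S` between `Smin` and `S0`).
#' @param n_lie Number of Lie derivatives probed (= number of flow time
#'   instants minus one); default: augmented dimension.
#' @param augment_params If `TRUE`, parameters are appended as constant
#'   states and the test reads as structural local identifiability.
#'   Temperature-law coefficients are collapsed to the effective rates at
#'   `temp`.
#' @param t_max Largest flow time probed (h).
#' @param rank_tol Singular values below `rank_tol * s_max` count as zero.
#' @param flag_tol A direction counts as inside the row space when the
#'   orthogonal residual of its projection is below `flag_tol`.
#' @param n_points Number of jittered evaluation points.
#' @param seed Seed for the point jitter (restores the RNG state).
#' @return An `observability_verdict`: list with `model_id`, `outputs`,
#'   `rank`, `dim`, `observable` (`TRUE`/`FALSE`/`NA` for indeterminate),
#'   `state_flags` (named logical: is each direction reconstructible),
#'   `singular_values` (from the first point), `augmented`.
#' @export
#' @examples
#' \donttest{
#' observability_rank("co2", c("S", "VDK"))
#' }
observability_rank <- function(model_id, outputs,
                               params = default_params(model_id),
                               temp = 19, S0 = 80, E0 = 0,
                               point = NULL, n_lie = NULL,
                               augment_params = FALSE, t_max = 12,
                               rank_tol = 1e-6, flag_tol = 0.05,
                               n_points = 3, seed = 101) {
  model_id <- .check_model_id(model_id)
  allowed <- .MODEL_VARS[[model_id]]
  bad <- setdiff(outputs, allowed)
  if (length(bad))
    stop("unknown output(s) for the ", model_id, " model: ",
         paste(bad, collapse = ", "))
  if (length(outputs) < 1) stop("at least one output required")
  theta_eff <- .effective_params(model_id, params, temp)
  states <- .MODEL_STATES[[model_id]]
  dim_z <- length(states) + if (augment_params) length(theta_eff) else 0
  if (is.null(n_lie)) n_lie <- dim_z
  stopifnot(n_lie >= length(states) - 1)
  times <- seq(t_max / (n_lie + 1), t_max, length.out = n_lie + 1)

  pts <- if (!is.null(point)) {
    list(point[states])
  } else {
    base <- .generic_point(model_id, params, S0)
    .with_seed(seed, lapply(seq_len(n_points), function(i)
      base * runif(length(base), 0.85, 1.18)))
  }

  ranks <- integer(length(pts))
  flags <- vector("list", length(pts))
  sv1 <- NULL
  for (i in seq_along(pts)) {
    O <- .obs_matrix(model_id, outputs, pts[[i]], theta_eff, temp, S0, E0,
                     times, augment = augment_params)
    dec <- svd(O)
    if (is.null(sv1)) sv1 <- dec$d
    r <- sum(dec$d > rank_tol * dec$d[1])
    ranks[i] <- r
    Vr <- dec$v[, seq_len(r), drop = FALSE]
    resid <- sqrt(pmax(0, 1 - rowSums(Vr^2)))
    flags[[i]] <- stats::setNames(resid < flag_tol, colnames(O))
  }
  agree <- length(unique(ranks)) == 1 &&
    all(vapply(flags[-1], identical, TRUE, flags[[1]]))
  rank <- ranks[1]
  verdict <- if (!agree) NA else rank == dim_z
  structure(list(model_id = model_id, outputs = outputs, rank = rank,
                 dim = dim_z, observable = verdict,
                 state_flags = flags[[1]], singular_values = sv1,
                 augmented = augment_params, ranks = ranks),
            class = "observability_verdict")
}

#' @export
print.observability_verdict <- function(x, ...) {
  label <- if (is.na(x$observable)) "indeterminate"
           else if (x$observable) "observable" else "not observable"
  mode <- if (x$augmented) "identifiability" else "observability"
  cat(sprintf("<observability_verdict> %s model, outputs [%s]: %s (%s, rank %d/%d)\n",
              x$model_id, paste(x$outputs, collapse = ", "), label, mode,
              x$rank, x$dim))
  if (!is.na(x$observable) && !x$observable) {
    miss <- names(x$state_flags)[!x$state_flags]
    cat("  unreconstructible direction(s):", paste(miss, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Observability report over several output sets
#'
#' Runs [observability_rank()] for each output set and returns a summary
#' table mirroring the usual presentation (output set, verdict).
#'
#' @param model_id `"biomass"` or `"co2"`.
#' @param output_sets List of character vectors of measured outputs.
#' @param ... Passed to [observability_rank()].
#' @return Data frame with columns `outputs`, `observable`, `rank`, `dim`,
#'   and `detail` (per-state flags for partially observable sets); the
#'   verdict objects are attached as attribute `"verdicts"`.
#' @export
observability_table <- function(model_id, output_sets, ...) {
  verdicts <- lapply(output_sets, function(o)
    observability_rank(model_id, o, ...))
  detail <- vapply(verdicts, function(v) {
    if (is.na(v$observable) || v$observable) return("")
    fl <- v$state_flags
    paste(paste0(names(fl), ": ", ifelse(fl, "Yes", "No")), collapse = ", ")
  }, "")
  out <- data.frame(
    outputs = vapply(output_sets, paste, "", collapse = ","),
    observable = vapply(verdicts, function(v)
      if (is.na(v$observable)) "indeterminate"
      else if (v$observable) "Yes" else "No", ""),
    rank = vapply(verdicts, function(v) as.integer(v$rank), 0L),
    dim = vapply(verdicts, function(v) as.integer(v$dim), 0L),
    detail = detail)
  attr(out, "verdicts") <- verdicts
  out
}
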