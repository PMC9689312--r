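# Weighted least-squares estimation: objective, multi-start Nelder-Mead
# search with Levenberg-Marquardt refinement, and the free/fixed parameter
# bookkeeping shared by the staged recipes.
#
# The objective is
#   J(theta) = sum_exp sum_i (y(ti) - ym(ti, theta))' W^-1 (y(ti) - ym(ti, theta))
# with W diagonal, W_jj = (max_i y_j(ti))^2 per experiment: a relative-error
# normalization in which each variable's residuals are scaled by its own
# measurement maximum.

#' Diagonal weighting matrix of a measurement set
#'
#' `W_jj = (max_i y_j(ti))^2` for each observed variable, off-diagonals
#' zero. Normalizing residuals by `W^-1` makes the objective dimensionless
#' and matches a relative error model in which the measurement error is
#' proportional to the maximum of each observed variable.
#'
#' @param dataset A `measurement_set`.
#' @return Diagonal numeric matrix with dimnames = observed variables.
#' @export
weight_matrix <- function(dataset) {
  vars <- dataset$variables
  maxima <- vapply(vars, function(v) {
    y <- dataset$data[[v]]
    if (all(is.na(y))) NA_real_ else max(abs(y), na.rm = TRUE)
  }, 0)
  if (any(is.na(maxima) | maxima == 0))
    stop("degenerate weight: variable(s) with no nonzero observation: ",
         paste(vars[is.na(maxima) | maxima == 0], collapse = ", "))
  W <- diag(maxima^2, nrow = length(vars))
  dimnames(W) <- list(vars, vars)
  W
}

#' Specify free and fixed parameters for a fit
#'
#' @param model_id `"biomass"` or `"co2"`.
#' @param free Character vector naming the free parameters `theta`. May
#'   contain model parameters, the constant rates `mu_max`/`r_vdk` (used in
#'   place of the temperature-law coefficients), and initial-condition
#'   names (`X0, S0, E0, CO2_0, VDK0`) for single-experiment fits.
#' @param init Full named vector of starting/fixed values; defaults to
#'   [default_params()] for the model. Must cover every name in `free`.
#' @param lower,upper Optional named bounds on the free parameters.
#'   Defaults span a factor 100 either side of `init` (sign-preserving);
#'   parameters with `init = 0` default to `[0, 1]`.
#' @return An object of class `param_spec` with elements `model_id`,
#'   `free`, `init`, `lower`, `upper`, `P`.
#' @export
param_spec <- function(model_id, free, init = NULL,
                       lower = NULL, upper = NULL) {
  model_id <- .check_model_id(model_id)
  if (is.null(init)) init <- default_params(model_id)
  init <- stats::setNames(as.numeric(init), names(init))
  stopifnot(length(free) >= 1)
  missing <- setdiff(free, names(init))
  if (length(missing))
    stop("free parameter(s) without an initial value: ",
         paste(missing, collapse = ", "))
  lo <- hi <- stats::setNames(numeric(length(free)), free)
  for (k in free) {
    v <- init[[k]]
    if (v == 0) {
      lo[k] <- 0; hi[k] <- 1
    } else {
      b <- sort(c(v / 100, v * 100))
      lo[k] <- b[1]; hi[k] <- b[2]
    }
  }
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo >= hi))
    stop("bounds must be finite with lower < upper")
  structure(list(model_id = model_id, free = free, init = init,
                 lower = lo, upper = hi, P = length(free)),
            class = "param_spec")
}

# Split a full value vector into model parameters and initial-condition
# overrides.
.split_theta <- function(full) {
  ic_names <- intersect(names(full), .IC_NAMES)
  list(params = full[setdiff(names(full), ic_names)],
       ic = full[ic_names])
}

.design_with_ic <- function(design, ic) {
  map <- c(X0 = "X0", S0 = "S0", E0 = "E0", CO2_0 = "CO2_0", VDK0 = "VDK0")
  for (k in names(ic)) design[[map[[k]]]] <- ic[[k]]
  design
}

# Model predictions for one measurement set at free-parameter value theta.
.predict_dataset <- function(theta, dataset, spec, rtol = 1e-8, atol = 1e-10) {
  full <- .merge_params(spec$init, stats::setNames(theta, spec$free))
  parts <- .split_theta(full)
  design <- .design_with_ic(dataset$design, parts$ic)
  traj <- integrate_model(spec$model_id, parts$params, design,
                          t_grid = dataset$times, rtol = rtol, atol = atol)
  observe(traj, dataset$variables, dataset$times)
}

# Stacked W-normalized residual vector over all datasets; NA observations
# are skipped. On integration failure, a constant large residual vector
# keeps derivative-free search alive (total J = penalty).
.wls_residuals <- function(theta, datasets, spec, W_list,
                           penalty = 1e6, rtol = 1e-8, atol = 1e-10) {
  res <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    ds <- datasets[[i]]
    pred <- try(.predict_dataset(theta, ds, spec, rtol, atol), silent = TRUE)
    if (inherits(pred, "try-error")) {
      n_tot <- sum(vapply(datasets, function(d)
        sum(!is.na(as.matrix(d$data[d$variables]))), 0L))
      return(rep(sqrt(penalty / n_tot), n_tot))
    }
    scale <- sqrt(diag(W_list[[i]]))
    r <- lapply(seq_along(ds$variables), function(j) {
      v <- ds$variables[j]
      rr <- (ds$data[[v]] - pred[[v]]) / scale[j]
      rr[!is.na(rr)]
    })
    res[[i]] <- unlist(r)
  }
  unlist(res)
}

.as_dataset_list <- function(datasets) {
  if (inherits(datasets, "measurement_set")) datasets <- list(datasets)
  stopifnot(all(vapply(datasets, inherits, TRUE, "measurement_set")))
  datasets
}

#' Weighted least-squares objective
#'
#' Sum over all experiments and sample instants of the `W`-normalized
#' squared residuals between data and model prediction; each experiment
#' uses its own weighting matrix from [weight_matrix()]. Missing
#' observations are skipped. An integration failure at `theta` returns a
#' large finite penalty (default `1e6`) instead of raising, which keeps
#' derivative-free searches alive.
#'
#' @param theta Numeric vector of free-parameter values (order =
#'   `spec$free`).
#' @param datasets A `measurement_set` or list of them.
#' @param spec A [param_spec()].
#' @param penalty Value returned on integration failure.
#' @return The scalar objective `J(theta) >= 0`.
#' @export
wls_objective <- function(theta, datasets, spec, penalty = 1e6) {
  datasets <- .as_dataset_list(datasets)
  W_list <- lapply(datasets, weight_matrix)
  sum(.wls_residuals(theta, datasets, spec, W_list, penalty = penalty)^2)
}

# Random starting points: log-uniform within bounds for sign-definite
# parameters (they span orders of magnitude), uniform when the bounds
# straddle zero.
.draw_starts <- function(n, spec) {
  out <- matrix(NA_real_, n, spec$P, dimnames = list(NULL, spec$free))
  for (k in spec$free) {
    lo <- spec$lower[[k]]; hi <- spec$upper[[k]]
    out[, k] <- if (lo > 0) {
      exp(runif(n, log(lo), log(hi)))
    } else if (hi < 0) {
      -exp(runif(n, log(-hi), log(-lo)))
    } else {
      runif(n, lo, hi)
    }
  }
  out
}

#' Multi-start WLS fit (simplex search + least-squares refinement)
#'
#' Step (a): `n_starts` Nelder-Mead searches of [wls_objective()], the
#' first from `spec$init`, the rest from log-uniform draws within the
#' bounds. Step (b): Levenberg-Marquardt refinement
#' ([minpack.lm::nls.lm()]) of the stacked weighted residual vector from
#' the best local minimum. Deterministic given `seed`.
#'
#' @param datasets A `measurement_set` or list of them.
#' @param spec A [param_spec()].
#' @param n_starts Number of simplex starts, `>= 1`.
#' @param seed Integer seed for the random starts (`NULL` = leave RNG).
#' @param nm_maxit Nelder-Mead iteration cap per start.
#' @param refine Run the Levenberg-Marquardt refinement (default `TRUE`).
#' @return A `fit_result`: list with `theta_hat` (named free-parameter
#'   estimates), `params` (full merged vector), `J_star`, `trace` (one row
#'   per start: starting and final objective, convergence code),
#'   `residuals` (per-experiment data frames of raw residuals),
#'   `bounds_hit`, `spec`, `n_obs` (total scalar observations), `M_total`
#'   (total sample instants), `N` (number of observed variables).
#' @export
multi_start_fit <- function(datasets, spec, n_starts = 20, seed = NULL,
                            nm_maxit = 500, refine = TRUE) {
  datasets <- .as_dataset_list(datasets)
  stopifnot(n_starts >= 1)
  if (!is.null(seed)) set.seed(seed)
  W_list <- lapply(datasets, weight_matrix)
  obj <- function(theta) {
    if (any(theta < spec$lower) || any(theta > spec$upper)) {
      excess <- sum(pmax(0, spec$lower - theta) / pmax(abs(spec$lower), 1e-8)) +
        sum(pmax(0, theta - spec$upper) / pmax(abs(spec$upper), 1e-8))
      return(1e6 * (1 + excess))
    }
    sum(.wls_residuals(theta, datasets, spec, W_list)^2)
  }

  starts <- rbind(spec$init[spec$free], .draw_starts(n_starts - 1L, spec))
  trace <- data.frame(start = seq_len(n_starts), J0 = NA_real_,
                      J_nm = NA_real_, convergence = NA_integer_)
  best <- NULL
  for (s in seq_len(n_starts)) {
    th0 <- starts[s, ]
    trace$J0[s] <- obj(th0)
    fit_s <- if (spec$P == 1) {
      optim(th0, obj, method = "Brent",
            lower = spec$lower, upper = spec$upper)
    } else {
      optim(th0, obj, method = "Nelder-Mead",
            control = list(maxit = nm_maxit))
    }
    trace$J_nm[s] <- fit_s$value
    trace$convergence[s] <- fit_s$convergence
    if (is.null(best) || fit_s$value < best$value) best <- fit_s
  }
  if (min(trace$J_nm) >= 1e6)
    stop("all starts failed to produce an integrable parameter set")

  theta_hat <- pmin(pmax(best$par, spec$lower), spec$upper)
  J_star <- obj(theta_hat)
  n_obs_total <- sum(vapply(datasets, function(d)
    sum(!is.na(as.matrix(d$data[d$variables]))), 0L))
  if (refine && n_obs_total > spec$P) {
    lm <- try(minpack.lm::nls.lm(
      par = theta_hat,
      fn = function(th) .wls_residuals(th, datasets, spec, W_list),
      lower = spec$lower, upper = spec$upper,
      control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
    if (!inherits(lm, "try-error") && lm$deviance <= J_star) {
      theta_hat <- stats::setNames(coef(lm), spec$free)
      J_star <- lm$deviance
    }
  }

  full <- .merge_params(spec$init, stats::setNames(theta_hat, spec$free))
  residuals <- lapply(datasets, function(ds) {
    pred <- .predict_dataset(theta_hat, ds, spec)
    r <- ds$data
    for (v in ds$variables) r[[v]] <- ds$data[[v]] - pred[[v]]
    r
  })
  tol_b <- 1e-8 * pmax(abs(spec$lower), abs(spec$upper), 1)
  bounds_hit <- (theta_hat - spec$lower < tol_b) |
    (spec$upper - theta_hat < tol_b)
  n_obs <- sum(vapply(datasets, function(d)
    sum(!is.na(as.matrix(d$data[d$variables]))), 0L))
  structure(list(theta_hat = stats::setNames(theta_hat, spec$free),
                 params = full, J_star = J_star, trace = trace,
                 residuals = residuals, bounds_hit = bounds_hit,
                 spec = spec, n_obs = n_obs,
                 M_total = sum(vapply(datasets, function(d)
                   length(d$times), 0L)),
                 N = length(datasets[[1]]$variables)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s model, %d free parameter(s), J* = %.6g\n",
              x$spec$model_id, x$spec$P, x$J_star))
  print(signif(x$theta_hat, 6))
  if (any(x$bounds_hit))
    cat("note: estimate at a bound for:",
        paste(names(x$theta_hat)[x$bounds_hit], collapse = ", "), "\n")
  invisible(x)
}
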