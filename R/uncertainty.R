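# Fisher-information-based uncertainty quantification.
#
#   FIM      = sum_i y_theta'(ti) Omega^-1 y_theta(ti),  Omega = eps2 * W
#   eps2     = J* / (M N - P)      (a-posteriori relative error estimate)
#   Sigma    = FIM^-1              (Cramer-Rao lower bound)
#   CV_k     = 100 sd_k / |theta_k|
#
# Sensitivities y_theta = d y_model / d theta are computed by central
# finite differences around the estimate; the integrator tolerances are
# tight enough that a relative step of 1e-5 sits comfortably between the
# truncation and rounding error floors.

#' Parametric output sensitivities by central finite differences
#'
#' Computes `d y_model / d theta` at every sample instant of every dataset
#' with central differences of relative step `rel_step`. If an integration
#' fails at a perturbed point, a one-sided difference is used with a
#' warning.
#'
#' @param theta_hat Named free-parameter values (order = `spec$free`).
#' @param datasets A `measurement_set` or list of them.
#' @param spec The [param_spec()] used for the fit.
#' @param rel_step Relative perturbation step (default `1e-5`).
#' @return List with one element per dataset: a numeric array of dimension
#'   `M x N x P` (sample instants x observed variables x parameters) with
#'   dimnames.
#' @export
sensitivities <- function(theta_hat, datasets, spec, rel_step = 1e-5) {
  datasets <- .as_dataset_list(datasets)
  theta_hat <- stats::setNames(as.numeric(theta_hat), spec$free)
  base <- lapply(datasets, function(ds)
    as.matrix(.predict_dataset(theta_hat, ds, spec)[ds$variables]))
  out <- lapply(seq_along(datasets), function(i) {
    ds <- datasets[[i]]
    arr <- array(NA_real_,
                 dim = c(length(ds$times), length(ds$variables), spec$P),
                 dimnames = list(NULL, ds$variables, spec$free))
    arr
  })
  for (k in seq_len(spec$P)) {
    h <- rel_step * max(abs(theta_hat[k]), rel_step)
    th_p <- th_m <- theta_hat
    th_p[k] <- th_p[k] + h
    th_m[k] <- th_m[k] - h
    for (i in seq_along(datasets)) {
      ds <- datasets[[i]]
      yp <- try(as.matrix(.predict_dataset(th_p, ds, spec)[ds$variables]),
                silent = TRUE)
      ym <- try(as.matrix(.predict_dataset(th_m, ds, spec)[ds$variables]),
                silent = TRUE)
      ok_p <- !inherits(yp, "try-error")
      ok_m <- !inherits(ym, "try-error")
      if (ok_p && ok_m) {
        out[[i]][, , k] <- (yp - ym) / (2 * h)
      } else if (ok_p) {
        warning("one-sided sensitivity for ", spec$free[k], call. = FALSE)
        out[[i]][, , k] <- (yp - base[[i]]) / h
      } else if (ok_m) {
        warning("one-sided sensitivity for ", spec$free[k], call. = FALSE)
        out[[i]][, , k] <- (base[[i]] - ym) / h
      } else {
        stop("integration failed at both perturbations of ", spec$free[k])
      }
    }
  }
  out
}

#' A-posteriori estimate of the relative measurement error
#'
#' `eps2 = J* / (M*N - P)`: the optimal objective divided by the number of
#' data points in excess of the number of estimated parameters.
#'
#' @param J_star Objective value at the optimum, `>= 0`.
#' @param M_total Total number of sample instants across experiments.
#' @param N Number of measured variables.
#' @param P Number of estimated parameters.
#' @return The scalar `eps2`.
#' @export
epsilon_hat2 <- function(J_star, M_total, N, P) {
  stopifnot(J_star >= 0)
  dof <- M_total * N - P
  if (dof <= 0)
    stop("M*N must exceed P: no residual degrees of freedom")
  J_star / dof
}

#' Fisher Information Matrix and Cramer-Rao covariance
#'
#' `FIM = sum_i y_theta'(ti) Omega^-1 y_theta(ti)` with
#' `Omega = eps2 * W`, summed over all sample instants (and datasets, when
#' lists are supplied). The covariance is `Sigma = FIM^-1`; when
#' `cond(FIM) > cond_tol` the Moore-Penrose pseudo-inverse is used instead
#' and flagged -- a practical-identifiability warning sign.
#'
#' @param sens Sensitivity array (`M x N x P`) from [sensitivities()], or
#'   the list of such arrays for several datasets.
#' @param W Weighting matrix from [weight_matrix()] (or list of them,
#'   matching `sens`).
#' @param eps2 A-posteriori error estimate from [epsilon_hat2()]. When
#'   `eps2 = 0` (perfect fit) the covariance is identically zero.
#' @param cond_tol Condition-number threshold for pseudo-inversion.
#' @return List with `FIM`, `Sigma`, `cond` (condition number), and
#'   `pseudo_inverse` flag.
#' @export
fim_and_covariance <- function(sens, W, eps2, cond_tol = 1e10) {
  if (!is.list(sens)) sens <- list(sens)
  if (!is.list(W)) W <- list(W)
  stopifnot(length(sens) == length(W), eps2 >= 0)
  P <- dim(sens[[1]])[3]
  pnames <- dimnames(sens[[1]])[[3]]
  # Accumulate the information with unit error variance (W only), then
  # scale: FIM = FIM_W / eps2.
  FIM_W <- matrix(0, P, P, dimnames = list(pnames, pnames))
  for (i in seq_along(sens)) {
    w_inv <- 1 / diag(W[[i]])
    a <- sens[[i]]
    for (m in seq_len(dim(a)[1])) {
      ym <- a[m, , , drop = TRUE]
      ym <- matrix(ym, nrow = dim(a)[2], ncol = P)
      keep <- apply(is.finite(ym), 1, all)
      if (!any(keep)) next
      yk <- ym[keep, , drop = FALSE]
      FIM_W <- FIM_W + t(yk) %*% (w_inv[keep] * yk)
    }
  }
  # enforce exact symmetry (accumulated rounding)
  FIM_W <- (FIM_W + t(FIM_W)) / 2
  # Parameters live on very different scales (1e-4 ... 1e1), which inflates
  # the raw condition number without any identifiability meaning. Invert in
  # correlation form: FIM_s = D FIM_W D with D = diag(1/sqrt(diag)), whose
  # conditioning reflects genuine parameter correlation; then
  # Sigma = eps2 * D FIM_s^-1 D. A parameter with zero diagonal information
  # is structurally invisible to the data and forces the pseudo-inverse.
  dg <- diag(FIM_W)
  zero_info <- dg <= 0
  s <- sqrt(ifelse(zero_info, 1, dg))
  Fs <- FIM_W / outer(s, s)
  sv <- svd(Fs, nu = 0, nv = 0)$d
  cond <- if (!any(zero_info) && min(sv) > 0) max(sv) / min(sv) else Inf
  pseudo <- !is.finite(cond) || cond > cond_tol
  Sigma_s <- if (pseudo) {
    warning("ill-conditioned FIM (scaled cond = ", signif(cond, 3),
            "): using pseudo-inverse; parameters may be practically ",
            "unidentifiable", call. = FALSE)
    MASS::ginv(Fs)
  } else {
    solve(Fs)
  }
  Sigma_W <- Sigma_s / outer(s, s)
  FIM <- if (eps2 > 0) FIM_W / eps2 else {
    m <- FIM_W * Inf
    m[FIM_W == 0] <- 0
    m
  }
  Sigma <- eps2 * Sigma_W
  dimnames(Sigma) <- dimnames(FIM_W)
  list(FIM = FIM, Sigma = Sigma, cond = cond, pseudo_inverse = pseudo)
}

#' Coefficients of variation
#'
#' `CV_k = 100 * sqrt(Sigma_kk) / |theta_k|` (percent). Undefined (NA) for
#' parameters estimated at exactly zero.
#'
#' @param Sigma Covariance matrix.
#' @param theta_hat Parameter estimates (same order).
#' @return Named numeric vector of CVs in percent.
#' @export
coefficients_of_variation <- function(Sigma, theta_hat) {
  sd <- sqrt(pmax(diag(Sigma), 0))
  cv <- ifelse(theta_hat == 0, NA_real_, 100 * sd / abs(theta_hat))
  stats::setNames(cv, names(theta_hat))
}

#' A-posteriori 95 percent error bars on the data
#'
#' Under the relative-error model the measurement standard deviation of
#' variable j is `sqrt(eps2 * W_jj)`, constant over the batch, so the 95
#' percent half-width is `1.96 * sqrt(eps2 * W_jj)`.
#'
#' @param W Weighting matrix from [weight_matrix()].
#' @param eps2 A-posteriori error estimate, `>= 0`.
#' @return Named vector of per-variable half-widths (data units).
#' @export
error_bars <- function(W, eps2) {
  stopifnot(eps2 >= 0)
  stats::setNames(1.96 * sqrt(eps2 * diag(W)), colnames(W))
}

#' Full uncertainty report for a fit
#'
#' Convenience wrapper chaining [sensitivities()], [epsilon_hat2()],
#' [fim_and_covariance()], [coefficients_of_variation()] and
#' [error_bars()] for a `fit_result`, pooling information across the
#' training datasets.
#'
#' @param fit A `fit_result` from [multi_start_fit()] or a staged fit.
#' @param datasets The datasets the fit was computed on.
#' @param rel_step Sensitivity step (see [sensitivities()]).
#' @param cond_tol Condition threshold (see [fim_and_covariance()]).
#' @return An `uncertainty_report`: list with `theta_hat`, `sens`, `eps2`,
#'   `FIM`, `Sigma`, `sd`, `cv` (percent), `error_bars` (per dataset),
#'   `cond`, `pseudo_inverse`.
#' @export
uncertainty_report <- function(fit, datasets, rel_step = 1e-5,
                               cond_tol = 1e10) {
  datasets <- .as_dataset_list(datasets)
  spec <- fit$spec
  sens <- sensitivities(fit$theta_hat, datasets, spec, rel_step = rel_step)
  W_list <- lapply(datasets, weight_matrix)
  eps2 <- epsilon_hat2(fit$J_star, fit$M_total, fit$N, spec$P)
  fc <- fim_and_covariance(sens, W_list, eps2, cond_tol = cond_tol)
  sd <- sqrt(pmax(diag(fc$Sigma), 0))
  cv <- coefficients_of_variation(fc$Sigma, fit$theta_hat)
  bars <- lapply(W_list, error_bars, eps2 = eps2)
  names(bars) <- vapply(datasets, function(d) as.character(d$design$id), "")
  structure(list(theta_hat = fit$theta_hat, sens = sens, eps2 = eps2,
                 FIM = fc$FIM, Sigma = fc$Sigma,
                 sd = stats::setNames(sd, names(fit$theta_hat)), cv = cv,
                 error_bars = bars, cond = fc$cond,
                 pseudo_inverse = fc$pseudo_inverse,
                 model_id = spec$model_id),
            class = "uncertainty_report")
}

#' @export
print.uncertainty_report <- function(x, ...) {
  cat(sprintf("<uncertainty_report> %s model, eps2 = %.4g, cond(FIM) = %.3g%s\n",
              x$model_id, x$eps2, x$cond,
              if (x$pseudo_inverse) " (pseudo-inverse)" else ""))
  tab <- data.frame(value = signif(x$theta_hat, 4),
                    sd = signif(x$sd, 3),
                    `CV %` = signif(x$cv, 2), check.names = FALSE)
  print(tab)
  invisible(x)
}
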