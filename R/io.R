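# Dataset I/O and the validation report (relative RMSE + residual J).
#
# Datasets travel as plain CSV with a controlled column vocabulary
# (time_h, X_gL, S_gL, E_gL, CO2_L, VDK_ppm, temp_C) plus an optional YAML
# sidecar (<path>.yml) carrying the design, noise descriptor and model id,
# so a written measurement set round-trips exactly.

# Column names used in delimited-text exports.
.COLUMN_MAP <- c(X = "X_gL", S = "S_gL", E = "E_gL", CO2 = "CO2_L",
                 VDK = "VDK_ppm")
.COLUMN_VOCAB <- c("time_h", "X_gL", "S_gL", "E_gL", "CO2_L", "VDK_ppm",
                   "temp_C")
.VAR_FROM_COLUMN <- stats::setNames(names(.COLUMN_MAP), .COLUMN_MAP)

#' Write a measurement set as delimited text
#'
#' Writes `<path>` (CSV: `time_h` plus one column per observed variable,
#' full precision, missing cells empty) and a YAML sidecar `<path>.yml`
#' with the design, noise descriptor, seed and model id.
#'
#' @param dataset A `measurement_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "measurement_set"))
  df <- dataset$data
  names(df) <- c("time_h", unname(.COLUMN_MAP[dataset$variables]))
  .write_csv_full(df, path)
  des <- dataset$design
  side <- list(model = dataset$model_id,
               design = list(id = des$id, duration = des$duration,
                             temperature = des$temperature, S0 = des$S0,
                             X0 = des$X0, E0 = des$E0, VDK0 = des$VDK0,
                             CO2_0 = if (is.na(des$CO2_0)) NULL else des$CO2_0),
               sigma_rel = dataset$sigma_rel,
               seed = if (is.null(dataset$seed)) NULL else dataset$seed,
               truncated_at_zero = dataset$truncated_at_zero,
               provenance = dataset$provenance)
  yaml::write_yaml(side, paste0(path, ".yml"))
  invisible(path)
}

#' Read a measurement set from delimited text
#'
#' Accepts only columns from the controlled vocabulary; unknown columns
#' and non-increasing times are errors. If the YAML sidecar written by
#' [write_dataset()] is present the design and noise descriptor are
#' restored; otherwise `model_id` must be supplied and a minimal design is
#' reconstructed from the data (provenance `"external"`).
#'
#' @param path CSV path.
#' @param model_id Required when no sidecar is found.
#' @return A `measurement_set`.
#' @export
read_dataset <- function(path, model_id = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  unknown <- setdiff(names(df), .COLUMN_VOCAB)
  if (length(unknown))
    stop("unknown column(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  if (!"time_h" %in% names(df)) stop("missing required column time_h")
  if (is.unsorted(df$time_h, strictly = TRUE))
    stop("time_h must be strictly increasing")
  side_path <- paste0(path, ".yml")
  side <- if (file.exists(side_path)) yaml::read_yaml(side_path) else NULL

  vars <- unname(.VAR_FROM_COLUMN[setdiff(names(df), c("time_h", "temp_C"))])
  data <- df[setdiff(names(df), "temp_C")]
  names(data) <- c("time_h", vars)

  if (!is.null(side)) {
    model_id <- side$model
    d <- side$design
    design <- experiment_design(d$id, d$duration, d$temperature, d$S0, d$X0,
                                E0 = d$E0 %||% 0, VDK0 = d$VDK0 %||% 0,
                                CO2_0 = d$CO2_0 %||% NA_real_)
    provenance <- side$provenance %||% "external"
    sigma_rel <- side$sigma_rel %||% NA_real_
    seed <- side$seed
  } else {
    if (is.null(model_id))
      stop("no sidecar descriptor found; supply model_id explicitly")
    model_id <- .check_model_id(model_id)
    temp <- if ("temp_C" %in% names(df)) df$temp_C[1] else NA_real_
    s0 <- if ("S" %in% vars && !is.na(data$S[1])) data$S[1] else 1
    x0 <- if ("X" %in% vars && !is.na(data$X[1])) data$X[1] else 1
    design <- suppressWarnings(
      experiment_design("external", duration = max(data$time_h),
                        temperature = temp, S0 = s0, X0 = x0))
    provenance <- "external"
    sigma_rel <- NA_real_
    seed <- NULL
  }
  bad <- setdiff(vars, .MODEL_VARS[[model_id]])
  if (length(bad))
    stop("column(s) not valid for the ", model_id, " model: ",
         paste(.COLUMN_MAP[bad], collapse = ", "))
  structure(list(model_id = model_id, design = design, times = data$time_h,
                 data = data, variables = vars,
                 sigma_rel = sigma_rel,
                 sigma_abs = stats::setNames(rep(NA_real_, length(vars)),
                                             vars),
                 seed = seed, truncated_at_zero = NA, provenance = provenance),
            class = "measurement_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Relative root-mean-square errors
#'
#' Per-variable `sqrt(mean(((y - yhat)/max_i|y|)^2))`: residuals are
#' normalized by each variable's measurement maximum, consistent with the
#' weighting of the estimation objective.
#'
#' @param predictions Data frame of model predictions with a `time_h`
#'   column aligned with the dataset's sample times.
#' @param dataset A `measurement_set`.
#' @return Named numeric vector of relative RMSEs.
#' @export
relative_rmse <- function(predictions, dataset) {
  common <- intersect(round(predictions$time_h, 9),
                      round(dataset$times, 9))
  if (!length(common)) stop("no common times between predictions and data")
  ip <- match(common, round(predictions$time_h, 9))
  id <- match(common, round(dataset$times, 9))
  vapply(dataset$variables, function(v) {
    y <- dataset$data[[v]][id]
    yhat <- predictions[[v]][ip]
    keep <- !is.na(y) & !is.na(yhat)
    m <- max(abs(dataset$data[[v]]), na.rm = TRUE)
    sqrt(mean(((y[keep] - yhat[keep]) / m)^2))
  }, 0)
}

#' Validation report: residual J and relative RMSEs
#'
#' Evaluates a parameter set against one or more datasets. In `"direct"`
#' mode the model is simulated from each dataset's design as-is. In
#' `"cross"` mode (the cross-validation protocol for a held-out batch)
#' only the initial conditions of each dataset are re-estimated via
#' [fit_initial_conditions()] before prediction; the parameters stay
#' fixed. Global RMSEs pool the normalized residuals of all experiments.
#'
#' @param params Full model parameter vector.
#' @param datasets A `measurement_set` or list of them.
#' @param model_id `"biomass"` or `"co2"`.
#' @param mode `"direct"` or `"cross"`.
#' @param ... Passed to [fit_initial_conditions()] in cross mode.
#' @return A `validation_report`: list with `per_experiment` (matrix of
#'   RMSEs, experiments x variables), `global` (per-variable pooled RMSE),
#'   `J` (WLS cost at the evaluated parameters), `mode`.
#' @export
validation_report <- function(params, datasets, model_id, mode = c("direct", "cross"),
                              ...) {
  mode <- match.arg(mode)
  model_id <- .check_model_id(model_id)
  datasets <- .as_dataset_list(datasets)
  params <- stats::setNames(as.numeric(params), names(params))

  preds <- vector("list", length(datasets))
  J <- 0
  pooled <- list()
  for (i in seq_along(datasets)) {
    ds <- datasets[[i]]
    full <- params
    if (mode == "cross") {
      icfit <- fit_initial_conditions(ds, params, ...)
      full <- icfit$params
    }
    spec_i <- param_spec(model_id, free = names(full)[1], init = full)
    pred <- .predict_dataset(full[1], ds, spec_i)
    preds[[i]] <- pred
    W <- weight_matrix(ds)
    for (j in seq_along(ds$variables)) {
      v <- ds$variables[j]
      r <- (ds$data[[v]] - pred[[v]]) / sqrt(W[j, j])
      r <- r[!is.na(r)]
      J <- J + sum(r^2)
      pooled[[v]] <- c(pooled[[v]], r)
    }
  }
  per_exp <- t(vapply(seq_along(datasets), function(i)
    relative_rmse(preds[[i]], datasets[[i]]),
    stats::setNames(numeric(length(datasets[[1]]$variables)),
                    datasets[[1]]$variables)))
  rownames(per_exp) <- vapply(datasets, function(d)
    as.character(d$design$id), "")
  global <- vapply(pooled, function(r) sqrt(mean(r^2)), 0)
  structure(list(per_experiment = per_exp, global = global, J = J,
                 mode = mode, model_id = model_id, predictions = preds),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s model, %s validation, J = %.4g\n",
              x$model_id, x$mode, x$J))
  tab <- rbind(x$per_experiment, global = x$global)
  print(signif(tab, 3))
  invisible(x)
}
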