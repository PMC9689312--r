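# Parameter containers for the two fermentation models.
#
# Parameters are stored as plain named numeric vectors carrying a class and
# a "model_id" attribute, so they can be subset, perturbed and rebuilt freely
# inside the estimation loops.

.MODEL_IDS <- c("biomass", "co2")

.PARAM_NAMES <- list(
  biomass = c("kS", "kE", "Smin", "deltaX", "kV", "kCO2", "a", "b", "c", "d"),
  co2     = c("kS", "kE", "KS", "Cpmax", "kV", "a", "b", "c", "d", "e")
)

# Names a parameter vector may use instead of the temperature-law
# coefficients: constant rates, used by the early stages of the staged fits.
.CONST_RATE_NAMES <- c("mu_max", "r_vdk")

# Initial-condition names recognised in a free-parameter specification.
.IC_NAMES <- c("X0", "S0", "E0", "CO2_0", "VDK0")

.check_model_id <- function(model_id) {
  match.arg(model_id, .MODEL_IDS)
}

#' Packaged default parameter sets
#'
#' Reads the parameter file shipped with the package for the requested model
#' and returns it as a parameter vector. These defaults are the package's
#' reference estimates for an ale fermentation between 17 and 28 degrees C
#' and serve as ground truth for synthetic-data recovery studies.
#'
#' @param model_id `"biomass"` or `"co2"`.
#' @return A named numeric vector of class `ferm_params`.
#' @export
#' @examples
#' default_params("biomass")[["kS"]]
default_params <- function(model_id = c("biomass", "co2")) {
  model_id <- .check_model_id(model_id)
  path <- system.file("extdata", paste0("params_", model_id, ".yaml"),
                      package = "brewkin", mustWork = TRUE)
  spec <- yaml::read_yaml(path)
  p <- unlist(spec$parameters)
  ferm_params(p, model_id)
}

#' Construct and validate a parameter vector
#'
#' @param values Named numeric vector covering the model's full parameter
#'   list (`kS, kE, Smin, deltaX, kV, kCO2, a, b, c, d` for the biomass
#'   model; `kS, kE, KS, Cpmax, kV, a, b, c, d, e` for the CO2 model).
#'   The temperature-law coefficients may be replaced by the constant rates
#'   `mu_max` and `r_vdk` (used by the staged-fit stages that ignore
#'   temperature dependence).
#' @param model_id `"biomass"` or `"co2"`.
#' @param check_range If `TRUE` (default), warn when the evaluated
#'   temperature laws go negative anywhere on the calibrated 17-28 C range.
#' @return The validated vector with class `ferm_params`.
#' @export
ferm_params <- function(values, model_id = c("biomass", "co2"),
                        check_range = TRUE) {
  model_id <- .check_model_id(model_id)
  values <- unlist(values)
  stopifnot(is.numeric(values), !is.null(names(values)))
  full <- .PARAM_NAMES[[model_id]]
  law_names <- setdiff(full, c("kS", "kE", "Smin", "deltaX", "kV", "kCO2",
                               "KS", "Cpmax"))
  stoich <- setdiff(full, law_names)
  missing_stoich <- setdiff(stoich, names(values))
  if (length(missing_stoich))
    stop("missing parameter(s): ", paste(missing_stoich, collapse = ", "))
  has_laws <- all(law_names %in% names(values))
  has_const <- all(.CONST_RATE_NAMES %in% names(values))
  if (!has_laws && !has_const)
    stop("parameter vector must contain either the temperature-law ",
         "coefficients (", paste(law_names, collapse = ", "),
         ") or constant rates (mu_max, r_vdk)")
  .validate_params(values, model_id, check_range = check_range)
  structure(values, class = "ferm_params", model_id = model_id)
}

.validate_params <- function(p, model_id, check_range = TRUE) {
  pos <- if (model_id == "biomass") {
    c("kS", "kE", "Smin", "kV", "kCO2")
  } else {
    c("kS", "kE", "KS", "Cpmax", "kV")
  }
  pos <- intersect(pos, names(p))
  if (any(p[pos] <= 0))
    stop("parameter(s) must be strictly positive: ",
         paste(pos[p[pos] <= 0], collapse = ", "))
  if (model_id == "biomass" && "deltaX" %in% names(p) && p[["deltaX"]] < 0)
    stop("deltaX (settling rate) must be nonnegative")
  if (model_id == "co2" && all(c("kS", "Cpmax") %in% names(p)) &&
      p[["kS"]] * p[["Cpmax"]] >= 1)
    warning("kS * Cpmax >= 1: residual sugar goes negative at the ",
            "carrying capacity", call. = FALSE)
  if (check_range) {
    tgrid <- seq(17, 28, by = 0.5)
    laws <- suppressWarnings(temperature_laws(model_id, tgrid, p))
    if (any(laws$mu_max < 0) || any(laws$r_vdk < 0))
      warning("temperature law negative somewhere on 17-28 C", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.ferm_params <- function(x, ...) {
  cat("<ferm_params> model:", attr(x, "model_id"), "\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

# Merge free-parameter values into a full parameter vector (no validation;
# used inside optimization loops where intermediate values may be wild).
.merge_params <- function(init, theta) {
  init[names(theta)] <- theta
  init
}
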