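# Shared fixtures: everything is generated in code at test time.

bio_truth <- function() default_params("biomass")
co2_truth <- function() default_params("co2")

# Coarse, fast training datasets (designs 2-4, sparse schedule) used where
# a full-resolution fit would be wasteful.
coarse_training <- function(model_id, params = default_params(model_id),
                            sigma_rel = 0, seed = NULL) {
  designs <- default_designs()[c("2", "3", "4")]
  seeds <- if (is.null(seed)) vector("list", 3) else as.list(seed + 0:2)
  lapply(seq_along(designs), function(i) {
    d <- designs[[i]]
    make_dataset(model_id, params, d, sigma_rel = sigma_rel,
                 seed = seeds[[i]],
                 times = sampling_schedule(d$duration, dt_early = 6,
                                           dt_late = 18))
  })
}

# Hand-built measurement set wrapper for arithmetic-level tests.
manual_dataset <- function(model_id, design, data, variables) {
  structure(list(model_id = model_id, design = design,
                 times = data$time_h, data = data, variables = variables,
                 sigma_rel = 0,
                 sigma_abs = stats::setNames(rep(0, length(variables)),
                                             variables),
                 seed = NULL, truncated_at_zero = FALSE,
                 provenance = "synthetic"),
            class = "measurement_set")
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
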