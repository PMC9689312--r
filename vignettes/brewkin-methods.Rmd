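---
title: "Methods: models, estimation and numerical choices in brewkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimation and numerical choices in brewkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brewkin)
```

## The two fermentation models

`brewkin` describes isothermal batch beer fermentation at two levels of
instrumentation.

The **biomass model** tracks yeast explicitly. An overall reaction
`kS S -> kE E + kV VDK + kCO2 CO2 + X` yields mass balances in which
sugar consumption, ethanol production, CO2 release and VDK production all
share the flux `mu_X * X`, so the ratios of any two of those rates are
fixed yield coefficients. Consequently `(S0-S)/kS`, `(E-E0)/kE` and
`(CO2-CO2_0)/kCO2` are equal along every trajectory — a linear first
integral the test suite checks to 1e-6 (it holds to ~1e-14 at the default
tolerances). Growth uses a Droop-type law
`mu_X = mu_max * max(0, 1 - Smin/S)`: batches reliably stall with
residual sugar left, and a threshold quota `Smin` captures that, unlike a
plain Monod factor which would always drive `S` to zero. Yeast settling
is a first-order sink `deltaX * X`. VDK is produced proportionally to
growth and re-assimilated at `r_VDK * VDK`.

The **CO2 model** removes the need for biomass measurements. Cumulative
CO2 volume follows `dCO2/dt = mu_X * CO2` with
`mu_X = mu_max * S/(KS+S) * (1 - CO2/(Cpmax*S0))`: Monod activation by
the remaining sugar plus a logistic brake whose carrying capacity
`Cpmax * S0` encodes the observed proportionality between total CO2 and
initial sugar. Sugar and ethanol are algebraic in CO2
(`S = S0 - kS*CO2`, `E = E0 + kE*CO2`), so the dynamic state is just
(CO2, VDK). The constraint `kS * Cpmax < 1` keeps residual sugar
positive at the carrying capacity; with the packaged defaults the
asymptotic residual sugar is `S0 (1 - kS*Cpmax)`, which a long-horizon
test compares against simulation.

Temperature is an exogenous constant per batch (the reference batches
are isothermal); it enters only through `mu_max = a ln(T) + b` and
`r_VDK = c ln(T) + d` (biomass model) or `c T^2 + d T + e` (CO2 model),
with `T` in degrees Celsius, calibrated over 17–28 °C. Outside that
range the laws can go negative; the package warns rather than errors,
since short extrapolations are common in exploratory use.

Two sign conventions deserve note. CO2 is treated as a *product* in
the biomass model (`dCO2/dt = +kCO2 mu_X X`, with `kCO2 > 0`), which is
what the reaction stoichiometry and the positivity of the packaged
`kCO2` require. And the CO2 model needs `CO2(0) > 0` (the logistic law
has a fixed point at zero), so the model default is `CO2(0) = 0.1` L,
overridable and estimable like any other initial condition.

## Parameters that matter

| Parameter | Units | Default | Role |
|---|---|---|---|
| `kS`, `kE`, `kV`, `kCO2` | per gX (biomass model) | 15.3, 6.31, 0.651, 37.1 | yields per unit biomass growth |
| `Smin` | g/L | 13.1 | sugar threshold where growth stops |
| `deltaX` | 1/h | 0.0167 | yeast settling rate |
| `kS`, `kE`, `kV` | per L CO2 (CO2 model) | 0.372, 0.162, 0.0174 | yields per litre CO2 |
| `KS` | g/L | 12.0 | Monod half-saturation (poorly identifiable) |
| `Cpmax` | L/g | 2.18 | CO2 carrying capacity per g initial sugar |
| `a`–`e` | 1/h (and °C powers) | see `default_params()` | temperature laws |

The packaged values are the package's reference estimates for an ale
fermentation; they serve both as simulation defaults and as the ground
truth of the synthetic-data recovery studies.

## Synthetic data: what it emulates and what it does not

`default_designs()` reproduces four reference batches (duration,
temperature, initial sugar and biomass). `sampling_schedule()` idealizes
the reference sampling protocol: every 2.5 h for the first 36 h, then
(in place of the irregular late sampling of a real campaign) a fixed 8 h
interval, always including the batch end. `make_dataset()` adds
zero-mean Gaussian noise with standard deviation
`sigma_rel * max_t(y_true)` per variable — the relative-error model that
also motivates the estimation weights — truncated at zero because
concentrations cannot be negative. The default `sigma_rel = 0.05` is a
typical relative accuracy for at-line beer analyzers and hobby-grade
online probes.

What the generator does **not** emulate: sensor-specific artifacts
(hydrometer drift, airlock bubble quantization), autocorrelated or
heteroscedastic-in-time errors, missing-at-random gaps, replicate
averaging, and any model mismatch — the data-generating process *is* the
fitted model. Passing recovery tests therefore demonstrates that the
pipeline is correct and the parameters are identifiable under the
stated designs and noise; it does not demonstrate that the models are
adequate for a particular real fermenter.

## Estimation machinery

The objective is `J(theta) = sum_exp sum_i r_i' W^-1 r_i` with per-
experiment diagonal weights `W_jj = (max_i y_j)^2` built from *measured*
maxima (the natural reading of a relative-error model; model-predicted
maxima would make the weights parameter-dependent). Missing cells are
skipped. If the ODE solver fails at a trial point the objective returns
a finite penalty (1e6) so derivative-free search continues.

`multi_start_fit()` runs `n_starts` Nelder–Mead searches — the first
from the supplied initial values, the rest from log-uniform draws within
the bounds, since the parameters span orders of magnitude — then refines
the best minimum with Levenberg–Marquardt (`minpack.lm::nls.lm`) on the
stacked weighted residual vector, which also enforces the bounds.
Default bounds span a factor 100 either side of the initial values.
Refinement is skipped when there are no residual degrees of freedom.

The temperature laws are identified in stages because fitting them from
a cold start is poorly conditioned. Biomass model: (a) all parameters
with *constant* `mu_max`, `r_VDK`; (b) the four law coefficients with
everything else frozen; (c) a global refit. CO2 model: (a) constant
rates with `KS` frozen at an arbitrary value (10 g/L) because its
practical identifiability is poor; (b) `KS` alone; (c) the five law
coefficients; (d) a global refit. Stage (a)'s constant rates start from
the supplied law evaluated at the mean training temperature. With a
single training temperature the laws are structurally unidentifiable:
the staged fitters warn and return the constant-rate fit, flagged.

Cross-validation of a held-out batch re-estimates *only* its initial
conditions (they are themselves measured with error) with all model
parameters frozen; `validation_report(mode = "cross")` wraps this.
Relative RMSEs normalize residuals by each variable's measurement
maximum, consistent with the objective; global RMSEs pool the
normalized residuals across experiments (rather than averaging
per-experiment RMSEs, which would weight short batches up).

## Uncertainty quantification

Sensitivities `d y / d theta` are computed by central finite differences
with relative step 1e-5; at the integrator tolerances (rtol 1e-8, atol
1e-10) this sits comfortably between the truncation and rounding error
floors, and a step-halving test guards the choice. Forward sensitivity
ODEs would be more elegant but buy nothing at these problem sizes.

`eps2 = J*/(MN - P)` pools all training experiments (M is the pooled
sample count), `FIM = sum y_theta' (eps2 W)^-1 y_theta`, and
`Sigma = FIM^-1` is the Cramér–Rao bound, from which per-parameter
standard deviations and coefficients of variation follow. One numerical
subtlety: the raw FIM's condition number is dominated by parameter
*units* (entries span 1e-4 to 1e1), so the package inverts in
correlation form `D FIM D`, `D = diag(1/sqrt(diag FIM))`, and reports
the condition number of that scaled matrix. Genuine rank deficiency
(confounded parameters, zero-information directions) still triggers a
Moore–Penrose pseudo-inverse with an explicit flag — a practical
identifiability warning, not a silent fix. A-posteriori 95 % error bars
are `1.96 sqrt(eps2 W_jj)`, constant per variable under the
relative-error model.

## Observability and identifiability

Local observability is a rank condition on the gradients of the outputs
and their Lie derivatives along the vector field. Computing those by
nested finite differencing is numerically hopeless beyond order two, so
the package probes the same row space through the flow: the matrix
`O[(t,j), i] = d y_j(t) / d x0_i`, assembled by central differences on
the integrator over a short sequence of times (up to 12 h), spans — by
the Lie-series expansion of the flow — the span of the Lie-derivative
gradients at a generic point. Directions are log-scaled and outputs
max-scaled so the singular values are comparable; with step 1e-3 and
rtol 1e-11 the measured gap between "structurally zero" and genuine
singular values exceeds nine decades, so the rank threshold
(1e-6 times the largest singular value) is uncritical. A state counts
as reconstructible when its basis direction lies in the row space
(projection residual below 0.05 — observed residuals are either ~0 or
~1). The test is repeated at three jittered mid-fermentation points
(all state components strictly positive, `S` between `Smin` and `S0`,
where no rate factor vanishes); disagreement yields the verdict
"indeterminate" rather than a guess.

Identifiability mode appends parameters as constant states. The
temperature-law coefficients are collapsed to the effective rates
`mu_max(T)`, `r_VDK(T)`: an isothermal batch only ever sees those two
numbers, so asking for `a` and `b` separately from one batch would make
every verdict trivially negative. With this convention the augmented
dimensions are 13 (biomass) and 9 (CO2), and the test reproduces the
expected structural picture: the parameters are identifiable exactly
when every state variable is measured, because each yield coefficient is
invisible without its corresponding output.

## Problem sizes and numerical defaults

The test suite and the acceptance script use: 201-point trajectories for
simulation checks; the standard sampling schedule (19–26 samples per
batch) for the recovery fits on designs 2–4 (~260–320 scalar
observations); 500 h horizons for the asymptote checks; 20 noisy
replicates at `sigma_rel = 0.05` for the coverage check of the
Cramér–Rao standard deviations; and 300 replicate draws for the
Monte-Carlo validation of the noise scale. Integrator defaults are
rtol 1e-8 / atol 1e-10 (lsoda), tightened to 1e-10/1e-12 where a test
asserts conservation to 1e-6 and to 1e-11/1e-13 inside the observability
probe. States are clipped to non-negative values only in reported
tables, never inside the integrator, preserving smoothness for the
finite-difference machinery.

## Known limitations

* Temperature is constant per batch; time-varying profiles (industrially
  common) are out of scope.
* The noise model is uncorrelated Gaussian with a per-variable constant
  scale; real probe errors drift and quantize.
* Multi-start Nelder–Mead plus refinement offers no global-optimality
  guarantee; the staged recipes mitigate but do not remove
  multi-modality.
* The observability verdicts are local and numerical — a deliberate,
  desk-scale proxy for symbolic analysis, generic-point sound but not a
  structural proof.
* `KS` of the CO2 model is practically weakly identifiable (large CV
  even at full rank); treat its point estimate accordingly.
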