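# brewkin

Kinetic modelling and parameter estimation of isothermal batch beer
fermentation.

During an ale fermentation, yeast converts wort sugars into ethanol and
CO2, while off-flavour vicinal diketones (VDK, e.g. diacetyl) are first
produced alongside growth and later re-assimilated. `brewkin` implements
two compact dynamic models of this process and the complete workflow
needed to identify them from batch time-series data — or, since such data
is rarely public, from synthetic data emulating a set of four reference
batch experiments (72–96 h, 19–28 °C, initial sugar 72–88 g/L).

## The models

**Biomass model** — five states (X biomass, S sugar, E ethanol, CO2, VDK):

    dX/dt   = (mu_X - deltaX) X          mu_X = mu_max * max(0, 1 - Smin/S)
    dS/dt   = -kS   mu_X X
    dE/dt   = +kE   mu_X X
    dCO2/dt = +kCO2 mu_X X
    dVDK/dt = kV mu_X X - r_VDK * VDK

Growth follows a Droop-type threshold law: fermentation stalls at a
residual sugar `Smin` (~13 g/L), as observed in practice. The settling
rate `deltaX` accounts for yeast sedimentation.

**CO2 model** — two dynamic states (CO2, VDK), with sugar and ethanol as
algebraic outputs (`S = S0 - kS*CO2`, `E = E0 + kE*CO2`):

    dCO2/dt = mu_X CO2        mu_X = mu_max * S/(KS+S) * (1 - CO2/(Cpmax*S0))
    dVDK/dt = kV mu_X CO2 - r_VDK * VDK

a Monod-activation times logistic-saturation law whose carrying capacity
`Cpmax * S0` ties the total CO2 released to the initial sugar. Only cheap
online sensors (airlock CO2 counter, tilt hydrometer) are needed to
identify it.

Both models make `mu_max` and `r_VDK` temperature-dependent
(`mu_max = a ln T + b`; `r_VDK = c ln T + d` or `c T^2 + d T + e`),
calibrated over 17–28 °C. Packaged defaults for all parameters ship as
YAML under `inst/extdata/`.

**Estimation.** A weighted least-squares objective
`J = sum_i (y_i - y_model)' W^-1 (y_i - y_model)` with `W_jj` the squared
per-variable measurement maxima (a relative-error model), minimized by
multi-start Nelder–Mead followed by Levenberg–Marquardt refinement.
Temperature laws are identified by staged recipes (constant rates first,
then law coefficients, then a global refit). Uncertainty comes from the
Fisher Information Matrix: `FIM = sum_i y_theta' Omega^-1 y_theta`,
`Sigma = FIM^-1` (Cramér–Rao), per-parameter coefficients of variation,
and a-posteriori 95 % error bars on the data. A numerical local rank test
decides which output sets make the state observable (the basis for
software sensors) and which make the parameters identifiable.

## Worked example

Fit the CO2 model to noisy synthetic data from the three training batches
(designs 2–4: 19, 21 and 28 °C) generated at 5 % relative noise:

```r
library(brewkin)
truth <- default_params("co2")
designs <- default_designs()[c("2", "3", "4")]
data <- lapply(seq_along(designs), function(i)
  make_dataset("co2", truth, designs[[i]], sigma_rel = 0.05, seed = 42 + i))

spec <- param_spec("co2", free = names(truth), init = truth)
fit  <- multi_start_fit(data, spec, n_starts = 1, nm_maxit = 50)
fit
#> <fit_result> co2 model, 10 free parameter(s), J* = 0.601213
#>           kS           kE           KS        Cpmax           kV ...
#>  0.371020000  0.161693000 13.790800000  2.162960000  0.017576200 ...

uncertainty_report(fit, data)
#> <uncertainty_report> co2 model, eps2 = 0.002444, cond(FIM) = 2.56e+05
#>            value       sd CV %
#> kS     0.3710000 0.005400  1.5
#> kE     0.1617000 0.002130  1.3
#> KS    13.7900000 5.670000 41.0
#> Cpmax  2.1630000 0.022500  1.0
#> kV     0.0175800 0.000414  2.4
#> ...
```

The yields `kS`, `kE`, `kV` and the carrying capacity `Cpmax` come back
within ~1 % of the generating values with small CVs; the half-saturation
constant `KS` is recovered but with a 41 % CV — the classic practical
identifiability weakness of Monod constants, which is why the staged
recipe (`staged_fit_co2()`) freezes it early on. `eps2 ≈ 0.0024 ≈ 0.05²`
recovers the generating noise variance.

Which sensors suffice to reconstruct the full state online?

```r
observability_rank("co2", c("S", "VDK"))
#> <observability_verdict> co2 model, outputs [S, VDK]: observable (observability, rank 2/2)
```

A command-line front end wraps the same pipeline
(`Rscript inst/cli/brewkin.R generate|simulate|fit|uncertainty|observability|validate ...`).

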