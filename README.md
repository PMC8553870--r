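# ednadvm

A one-dimensional mechanistic model of the vertical distribution of
environmental DNA (eDNA) shed by mesopelagic organisms that perform diel
vertical migration (DVM). Water samples detect eDNA where it drifted, not
necessarily where the animal was; this package quantifies that gap for a
migrating source in a stratified water column, for ecologists designing or
interpreting depth-resolved eDNA surveys (qPCR-style single-species
concentrations).

## The model

Organisms reside near 500 m by day and 50 m by night, migrating in 3-hour
constant-speed ramps tied to seasonal sunrise/sunset (NOAA solar equations,
2019, 42.35° N 71.05° W). They shed eDNA continuously as two size classes —
large particles C_LP (settle at w_s, break down into small particles at
rate δ) and small particles C_SP (neutrally buoyant) — governed by

    ∂C_LP/∂t = −w_v ∂C_LP/∂z + ∂/∂z(κ_z ∂C_LP/∂z) − k C_LP − δ C_LP + w_s ∂C_LP/∂z + S_LP
    ∂C_SP/∂t = −w_v ∂C_SP/∂z + ∂/∂z(κ_z ∂C_SP/∂z) − k C_SP + δ C_LP + S_SP

with first-order decay k (constant or k = 0.05 + 0.0014·T 1/h), prescribed
seasonal diffusivity/temperature/advection profiles, a no-flux surface and a
zero-gradient open bottom at 1500 m. A compiled operator-split solver
(exact exponential kinetics, upwind transport, implicit diffusion) keeps
full seasonal runs fast and mass-conserving to a logged budget.

On top of the solver the package provides: analytic decay/transport scales
(T90 = −ln(0.1)/k_avg; L_mix, L_advect, L_settle), depth-bin metrics
(surface 0–100 m, mid 100–450 m, deep 450–550 m), the 972-run factorial
sensitivity design, the 44-run percent-migrating study, and inversion of
the percent of migrating individuals P_m from the surface-to-deep
concentration ratio C_s/C_d via a monotone calibration curve.

## Worked example

```r
library(ednadvm)

sim <- run_simulation(season_spec("JAS"), pm = 0.5,
                      config = solver_config("desk"))
summarize_bins(sim)
#>       bin          min      mean      max       sd
#> 1 surface 5.018783e+00 14.896394 49.99205 5.562265
#> 2     mid 4.185598e-77  9.507269 20.28670 1.886840
#> 3    deep 5.000795e+01 75.596337 88.16039 5.589891
```

A summer run with half the cohort migrating keeps ~76 % of the eDNA in the
deep layer and ~15 % in the surface layer on time average — the bimodal
signature of DVM, with the deep peak dominating because organisms spend
more of the day at depth and decay is slower in cold water. (The run starts
from an empty column, so the first-day transient sets the min/max columns;
means equilibrate within ~2 days.)

```r
length_scales(k_avg = 0.06, kappa_v = 1e-3, w_vm = 1e-4, w_s = 10)
#> $T90      38.37642   # hours
#> $L_mix    11.75370   # m
#> $L_advect 13.81551   # m
#> $L_settle 15.99017   # m
```

Physical processes move eDNA only ~10–20 m before 90 % of it decays, so a
measured profile closely mirrors where the organisms shed it.

```r
cal <- build_pm_calibration("JAS", config = solver_config("desk"))
invert_pm(0.19, cal)   # a measured Cs/Cd of 0.19 -> ~50 % migrating
```

A command-line front end with `run`, `sweep`, `pm-curve`, `invert-pm` and
`scales` subcommands is installed at `inst/cli/edna`.

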