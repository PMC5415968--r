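# lnpkinetics

Kinetic modeling of lipid-nanoparticle (LNP) mediated siRNA delivery:
simulate, fit and rank delivery vehicles and siRNA cargoes in silico.

Getting an siRNA from the culture medium to a loaded RISC complex is a
chain of kinetic bottlenecks — uptake, endosomal escape, RISC loading —
and the slowest link determines how much target mRNA is silenced.
`lnpkinetics` implements a compact five-species ODE model of that chain
for cells treated with an siRNA–LNP dose, and the tooling a screening
workflow needs around it: unit-aware configuration, deterministic
simulation of the three standard readouts (relative mRNA knockdown,
Ago2-bound siRNA, cell-associated siRNA), forward-sensitivity analysis
and parameter scans, bounded multi-start least-squares fitting of rate
constants from time-course data, and a synthetic-data generator so the
whole loop is testable without wet-lab input.

## The model

Species (molecules per cell): endosomal particles `N`, free cytoplasmic
siRNA `S`, Ago2-bound siRNA `SR`, active RISC–mRNA complex `SRM`, target
transcript `M`; extracellular pool `E` constant, free RISC
`R = max(R0 − SR − SRM, 0)`.

    dN/dt   = k1·E − (k2_eff(t) + k3)·N
    dS/dt   = k2_eff(t)·N − k5·S − k4·S·R
    dSR/dt  = k4·S·R − k6·M·SR
    dSRM/dt = k6·M·SR − k7·SRM
    dM/dt   = k8 − k9·M − k7·SRM

`k2_eff(t)` is a Heaviside-switched escape rate: zero before the
vehicle's escape-onset time `t_delay`, `k2` afterwards — LNPs show a 1–2 hr
lag before any silencing machinery engages, and the step reproduces it.
Without silencing, `M` rests at its steady state `k8/k9` = 100 copies per
cell, so knockdown `M(t)/M(0)` starts at exactly 1. A vehicle is
characterized by (k1, k2, k3, t_delay); an siRNA cargo by k4 — which is
what makes vehicle × cargo parameter transfer work.

## Worked example

Rank the shipped vehicle panel by simulated 24-hr silencing of a 10 nM
dose over 10,000 cells:

```r
library(lnpkinetics)
rank_vehicles(vehicle_fixtures())
#>               name relative_mrna_end t_half_knockdown_hr t_half_ago2_hr status
#> 1 LNP(1,3)-diether         0.6503831            13.81076       4.552688     ok
#> 2          RNAiMAX         0.7905837            14.94980       4.281181     ok
#> 3            LNP05         0.8878844            16.29029       4.719492     ok
#> 4           LNP201         0.9650472            16.21682       4.271842     ok
```

`relative_mrna_end` is M(24 hr)/M(0): the (1,3)-diether formulation
leaves 65% of the target transcript — the deepest knockdown of the
panel, consistent with its fast escape (k2 = 0.01/hr, onset 1.25 hr) —
while the reference LNP201 barely silences (96.5% remaining) because its
escape rate is 20-fold smaller. The half-effect columns summarize
kinetics: time to half of the knockdown excursion and to half of the
6-hr Ago2-binding plateau.

Fit an escape rate from (here: synthetic) knockdown data and inspect it:

```r
spec <- experiment_spec()                     # 10 nM, 3e-4 L, 1e4 cells
truth <- vehicle_fixtures()$RNAiMAX$parameters
data <- generate_timecourse(spec, truth, seed = 101)   # 10 pts x 10 reps, 5% noise
fit <- fit_vehicle(data, spec, truth, free = "k2", seed = 101)
fit$estimates[["k2"]]
#> [1] 0.0039403
```

0.00394/hr against a generating value of 0.004/hr — recovered within
1.5% from hundred noisy records. Sensitivity analysis says why escape is
the constant worth engineering:

```r
rank_parameters(forward_sensitivities(spec, truth))[1:3, ]
#   escape (k2) ranks first, ahead of RISC loading (k4) and uptake (k1)
```

A thin command-line wrapper covers the same workflow
(`inst/cli/lnpkin simulate|generate|fit|scan|sensitivity|rank`); every
file it writes gets a JSON manifest sidecar recording parameters, seed
and package version. See the vignette
(`vignettes/modeling-sirna-delivery.Rmd`) for the model's assumptions,
unit conventions, fitting design and limitations.

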