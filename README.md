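# commsel

Individual-based simulation of **artificial selection on a two-species
microbial community**, for researchers designing community-level selection
experiments (directed evolution of ecosystems) or studying when such
selection can work at all.

## The problem and the model

A *Helper* species H digests an abundant waste substrate and releases a
Byproduct B while growing; a *Manufacturer* species M needs both B and a
shared Resource R, and diverts a fraction *f*<sub>P</sub> of its potential
growth into a Product P that the experimenter values. The community
function under selection is *P(T)*, the Product accumulated while a
low-density "Newborn" culture grows into an "Adult" over maturation time
*T*. Natural selection inside each community favors cells with low
*f*<sub>P</sub> (cheaters); the experimenter's between-community selection
favors high *P(T)*. Whether the experimenter wins depends on the regimen:
how Adults are scored, which reproduce, and how precisely they are split
into the next cycle's Newborns.

The scaled dynamics are

    dH/dt = gH(R) H − δH H                 gH: Monod in R
    dM/dt = (1−fP) gM(R,B) M − δM M        gM: Mankad–Bungay in R and B
    dP/dt = fP gM(R,B) M
    dR/dt = −cRM gM M − cRH gH H
    dB/dt = gH H − cBM gM M

with `gM = gMmax · RM BM/(RM+BM) · (1/(RM+1) + 1/(BM+1))`,
`RM = R/K_MR`, `BM = B/K_MB`. On top of this ODE skeleton the simulator
tracks every cell individually: deterministic biomass growth, division at
biomass 2, stochastic death, and phenotype-altering mutation (50% null;
otherwise bilateral-exponential effects, means +5.0% / −6.7%, exact
inverse-CDF sampling, optional diminishing-returns epistasis). Community
reproduction implements the lab procedures: volumetric pipetting,
biomass- or cell-number sorting, single-determinant fixing, and fixed-fold
dilution; selection strategies are top-dog, top-tier, and a random
control. Everything is reproducible from one master seed, and any archived
community can be replayed bit-identically.

Deterministic analyses accompany the simulator: the community-function
landscape over (*f*<sub>P</sub>, Newborn composition), the closed-form
steady-state composition (1−*f*<sub>P</sub>)/(1−*f*<sub>P</sub>+*c*<sub>BM</sub>),
the serial-batch cycle map, the M-monoculture optimum, and the Newborn
fluctuation statistics of pipetting.

## Worked example

```r
library(commsel)

# where is community function maximized, were fP heritable and composition
# controllable?
land <- community_function_landscape(hm_params(), prescan = TRUE)
land
#> <landscape_result> optimum P(T) = 2736 at fP = 0.41, phiM(0) = 0.54

# twenty cycles of top-dog selection with cell sorting, 30 communities
cfg <- selection_config(n_tot = 30, n_cycles = 20, master_seed = 7,
                        reproduction = reproduction_spec("sort_biomass"))
run <- run_selection(cfg)
run
#> <commsel_run> 20 cycles x 30 communities | top_dog + sort_biomass | seed 7
#>   ancestral P(T) = 801.6
#>   final cycle 20: Pbar(T) = 788, fPbar(T) = 0.1592
```

The landscape says the community could in principle make `P*(T) = 2736`
units of Product if Manufacturers paid a cost of 0.41 and Newborns were
assembled at 54% M biomass. The run shows selection actually moving: with
a cell sorter fixing Newborn biomass and composition (so that community
function tracks its heritable determinant, the mean cost), the chosen
Adults' average *f*<sub>P</sub> climbs from 0.13 to 0.159 within twenty
cycles. Swap `"sort_biomass"` for `"pipetting"` and the climb stalls —
the central phenomenon the package exists to explore. Scenario presets
(`preset()`) cover the standard regimens: sorting vs pipetting, top-tier
strength scans, measurement noise, fixed-fold dilution in excess
Resource, per-capita scoring, monoculture group selection, mutualistic
communities, pregrowth founding.

A thin CLI wrapper ships at `inst/cli/commsel`
(`commsel run --config FILE --out DIR`, `commsel landscape`,
`commsel replay`, ...).

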