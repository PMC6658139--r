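---
title: "Simulating artificial selection on Helper-Manufacturer communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating artificial selection on Helper-Manufacturer communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commsel)
```

## The model

`commsel` simulates cycles of artificial selection on a two-species
microbial community. A **Helper** (H) digests an abundant waste substrate
and, while growing, releases a **Byproduct** (B) at no cost to itself. A
**Manufacturer** (M) needs that Byproduct and a shared **Resource** (R) to
grow, and diverts a fraction $f_P$ of its potential growth into a
**Product** (P) of value to the experimenter. The community function under
selection is $P(T)$, the Product accumulated while a low-density *Newborn*
culture matures into an *Adult* over time $T$.

All quantities are scaled: Resource in units of the amount supplied to one
Newborn, Byproduct in units of the amount released per H biomass grown,
Product in units of the amount made at the cost of one M biomass. The
coupled continuous dynamics are

$$
\begin{aligned}
\dot H &= g_H(R)\,H - \delta_H H, &
\dot M &= (1-f_P)\,g_M(R,B)\,M - \delta_M M, \\
\dot P &= f_P\, g_M(R,B)\, M, &
\dot R &= -c_{RM}\, g_M M - c_{RH}\, g_H H, \\
\dot B &= g_H H - c_{BM}\, g_M M, &&
\end{aligned}
$$

with Monod growth for H, $g_H = g_{H\max} R/(R + K_{HR})$, and
dual-substrate Mankad-Bungay growth for M,

$$
g_M = g_{M\max}\,\frac{R_M B_M}{R_M + B_M}
\left(\frac{1}{R_M + 1} + \frac{1}{B_M + 1}\right),
\qquad R_M = R/K_{MR},\; B_M = B/K_{MB}.
$$

Resource consumption follows *potential* growth ($g_M M$, not
$(1-f_P) g_M M$): biomass diverted into Product still costs Resource. A
mutualistic variant multiplies $g_H$ by $e^{-B/B_0}$ (Byproduct inhibits
H); `B0 = NULL` gives the commensal model.

Affinities are stored as $1/K$ throughout so that a null mutation ("zero
affinity") is an ordinary parameter value; every rate law is finite at
zero.

### Parameters

`hm_params()` carries the phenotypes and fixed parameters. The
`"preadapted"` set puts every growth parameter at its evolutionary upper
bound ($g_{H\max}=0.3$, $g_{M\max}=0.7$, $1/K_{HR}=5$, $1/K_{MR}=3$,
$1/K_{MB}=0.03$) with $f_P = 0.13$; `"ancestral"` is the pre-evolution
state ($g_{H\max}=0.25$, $g_{M\max}=0.58$, all affinities at 1x,
$f_P=0.1$). Consumption coefficients ($c_{RM}=c_{RH}=10^{-4}$,
$c_{BM}=1/3$) and death rates ($\delta_H = 1.5\times10^{-3}$,
$\delta_M = 3.5\times10^{-3}$, 0.5% of the respective maximal growth
rates) stay constant through evolution: element-to-biomass conversion and
basal mortality are not expected to evolve quickly, and death is small
against growth. With $c = 10^{-4}$ the Resource in one Newborn supports at
most $10^4$ biomass; `R0 = 10` (the fast-Helper scenario, upper bound
$g_{H\max} = 0.8$) raises that to $10^5$.

## The individual-based layer

Within a community every cell is tracked individually: its species, its
biomass (*length* $L$, growing from 1 to 2 before division), and its own
heritable phenotypes. Maturation advances in steps of
$\Delta\tau = 0.05$:

1. **Chemistry.** $R$ and $B$ evolve over the step with all biomasses
   frozen at their start-of-step values, together with one cumulative
   growth integral $\int g\,dt$ per phenotype group, solved as augmented
   states of one ODE system (adaptive Dormand-Prince RK45, `rtol = 1e-6`,
   `atol = 1e-9`, states clipped at 0). Cells with bitwise-identical
   growth-relevant parameters form one group; $f_P$ does not enter the
   chemistry because consumption follows potential growth.
2. **Growth.** $L \leftarrow L e^{\int g_H dt}$ for H;
   $L \leftarrow L e^{(1-f_P)\int g_M dt}$ for M, with Product accruing
   per cell as $\frac{f_P}{1-f_P}\Delta L$. At $f_P = 1$ the analytic
   limit applies ($\Delta L = 0$, $\Delta P = L\int g_M dt$) — mutation
   can push $f_P$ to its upper bound 1, which we clamp at exactly 1.
3. **Death.** Each cell dies independently with probability
   $\delta\,\Delta\tau$.
4. **Division.** Survivors with $L \ge 2$ split into two cells of length
   $L/2$; the daughter sits immediately after the mother, so replay is
   order-deterministic. A cell divides at most once per step (at
   $\Delta\tau = 0.05$ a length of 4 is unreachable).
5. **Mutation.** Every mutable phenotype of both fresh cells mutates
   independently with probability $P_{mut} = 2\times10^{-3}$ per
   division. A mutation is null (phenotype 0) with probability 0.5;
   otherwise the phenotype is multiplied by $1+\Delta$ with $\Delta$
   drawn by exact inverse-CDF sampling from a bilateral exponential
   (enhancing mean $s_+ = 0.050$, diminishing mean $s_- = 0.067$,
   truncated at $\Delta = -1$). Results clamp to the evolutionary
   bounds. Optional diminishing-returns epistasis rescales the means for
   $f_P$ mutations by $1 + g(f_P/f_{P,\mathrm{init}} - 1)$.

The whole loop runs in compiled code; all randomness flows through R's
RNG, so a community's maturation is bit-reproducible from its logged
seed. The fully coupled ODE system (`deterministic_trajectory()`, solved
independently by `deSolve::lsoda` with a compiled right-hand side) serves
both as the engine for the deterministic analyses and as the oracle the
agent layer is tested against: with mutation off, Adult biomass and
$P(T)$ agree within 1% at $\Delta\tau = 0.05$, the residual being
operator-splitting error.

## Selection cycles

`run_selection()` wires the full protocol: `n_tot` (default 100) Newborns
— 40 H + 60 M cells of biomass 1 each — mature for $T = 17$ (about six
doublings; Resource deliberately not exhausted), Adults are scored by
$P(T)$ (or $P(T)/M(T)$), optionally perturbed by Gaussian measurement
noise scaled to the ancestral $P(T)$, and the chosen Adults are split
into the next cycle's Newborns:

* **pipetting** — every cell gets a uniform random integer in
  $1..n_D$, $n_D = \lfloor BM/BM_{target}\rfloor$; Newborn biomass and
  composition fluctuate (SD of biomass
  $\sqrt{BM_{target}\bar L} \approx 12$).
* **sort_biomass / sort_cellnumber** — a cell sorter fixes Newborn
  biomass and species composition (closest-without-exceeding fill;
  skipped cells stay available, draws are disjoint until the Adult is
  exhausted).
* **fix_BM_only / fix_phiM_only** — fix one determinant, let the other
  fluctuate.
* **fixed_fold** — constant dilution fold (the failure mode under excess
  Resource).

Strategies: **top_dog** (best Adult contributes all it can, then the
runner-up, the last batch trimmed by a uniform random subset without
replacement), **top_tier** (best `n_chosen` contribute `n_tot/n_chosen`
each; `n_tot` must be divisible by `n_chosen`), **random_control**. Ties
break toward the lower community index; undefined scores (extinct M under
per-capita scoring) rank last. Every per-community seed and per-stage
seed derives from the master seed by a counter scheme, so results are
independent of execution order and any archived community can be
replayed in isolation (`replay_community()`).

## Deterministic analyses

* `community_function_landscape()` — $P(T)$ over the
  $99\times99$ grid $f_P = 0.01i$, $\phi_M(0) = 0.01j$ at $BM(0)=100$.
  With the preadapted parameters the unique maximum sits at
  $f_P^* = 0.41$, $\phi_M^*(0) = 0.54$. A 0.05-resolution prescan with
  local 0.01 refinement returns the same argmax in a fraction of the
  time; the full grid remains the reference.
* `steady_state_phiM()` — when Byproduct is depleted by the end of a
  cycle (valid for $f_P \lesssim 0.4$),
  $\phi_{M,SS} = (1-f_P)/(1-f_P+c_{BM})$; 0.64 at $f_P=0.41$. The
  iterated serial-batch map (`cycle_map_phiM()`) converges to within
  0.005 of this value for $f_P \le 0.4$ and flags M extinction
  ($\phi_M < 1/BM_{target}$) at high cost.
* `monoculture_optimum()` — grid search of deterministic $P(T)$ for an
  M group founded by one cell in excess Byproduct. "Excess" is
  implemented as the exact saturating limit ($g_M$ Monod in R alone)
  rather than a large finite Byproduct amount, avoiding consumption
  bookkeeping of an arbitrary constant. The profile is flat to ~0.2%
  between $f_P = 0.12$ and $0.15$; at `rtol = 1e-6` the argmax lands at
  0.138 (0.14 on the 0.01 grid), one grid step from the commonly quoted
  0.13 — at this flatness the argmax is sensitive to solver tolerance.
  Either way the monoculture optimum sits far below the community
  optimum 0.41, which is the scientific point: $\int g_M dt$ is larger
  in monoculture, and the optimal cost is approximately its reciprocal
  (`optimal_fP_approx()`).
* `newborn_fluctuation_stats()` — the pipetting fluctuation formulas.
  Note the ratio variance
  $\phi_M(1-\phi_M)^{-3}\bar L/BM_{target}$ is a first-order
  (delta-method) result: at $BM_{target} = 100$ the raw simulated
  variance runs ~25% above it, and the package validates the formula at
  $BM_{target} = 500$ where the expansion holds.

## Pregrowth of the founder monoculture

`pregrow_founder()` models growing the ancestral M clone from one cell
to $\sim 10^7$ ($2^{23}$ contributor doublings) before inoculating the
first cycle. Contributors ($f_P = 0.13$) grow at 0.87 times the null
rate; at each division a conversion to null is drawn with probability
$10^{-3}$. Because contributors divide synchronously, the process is
represented exactly by cohorts: a null cohort born at generation $k$
has completed $\lfloor (23-k)/0.87 \rfloor$ doublings by the end. Two
conversion conventions exist in the literature the model draws on — the
newborn daughter only, or mother and daughter independently. The
daughter-only convention (the default) gives a mean null load of
~2.5%, consistent with the commonly quoted ~3%; mother-and-daughter
(`convert = "both"`) doubles the load to ~5.5%. The null fraction is
strongly right-skewed (median ~1.2%): a conversion in the first few
generations produces a jackpot monoculture dominated by nulls, which is
why many replicates are needed for a stable mean.

## What the simulations do and do not show

The synthetic communities emulate the qualitative machinery of
artificial community selection: heritable ($\bar f_P(0)$) versus
non-heritable ($BM(0)$, $\phi_M(0)$, measurement error) determinants of
community function, intra- versus inter-community selection, and the
interaction of reproduction precision with selection strength. They do
not emulate real-culture features such as lag and stationary phases
(maturation stops short of Resource exhaustion by design), spatial
structure, gene-level genetics, or evolving consumption stoichiometry;
passing tests support the selection-regimen logic, not quantitative
predictions for any particular organism.

The regimen-comparison properties in the test suite run scaled down for
desk runtime, a configuration change only: 30 communities, 100 cycles,
three seeds for the reproduction-method and selection-strength
contrasts (trend and ordering statistics on $\bar f_P$); 10 communities
for the excess-Resource scenarios (6 cycles of fixed-fold dilution, 60
cycles of the fast-Helper contrast). At this scale the crash endpoints
(M extinction under per-capita scoring, Helper takeover under
pipetting) are probed as directions of effect — which arm's cost
ratchets, whose $\phi_M$ erodes, whether sorting holds the evolved
Helper rate below the Manufacturer's — because the full divergence of
the published scenarios needs thousands of cycles. Full-scale runs use
the shipped presets unchanged.

## Numerical choices

* Within-step chemistry: hand-written adaptive RK45 in C++ — with
  biomasses frozen over $\Delta\tau = 0.05$ and rates $\le 0.8$ the
  step system is non-stiff, and an in-loop compiled solver keeps a
  full maturation near 10 ms. The coupled analyses use `lsoda`
  (stiff-capable) instead, keeping the two code paths independent.
* Tolerances `rtol = 1e-6`, `atol = 1e-9` everywhere; $R$ and $B$ are
  clipped at 0 (R can approach 0 at long $T$).
* Phenotype grouping for the chemical solve uses exact bitwise equality
  — mutation creates discrete classes, so grouping is lossless.
* Degenerate inputs: an extinct community continues through the
  remaining steps with chemistry only (nothing changes without cells)
  and is flagged; `fP = 1` uses the analytic Product limit; sorting
  methods that exhaust an Adult return fewer Newborns and the cycle
  tops up from the next-ranked Adults.
* CSV archives store numbers at `%.17g`, so `read(write(x))`
  round-trips exactly.

## A worked example

```{r example, eval = FALSE}
library(commsel)

# deterministic reference: the community-function landscape
land <- community_function_landscape(hm_params(), prescan = TRUE)
land
#> <landscape_result> optimum P(T) = 2736 at fP = 0.41, phiM(0) = 0.54

# twenty cycles of top-dog selection with cell sorting, 30 communities
cfg <- selection_config(n_tot = 30, n_cycles = 20, master_seed = 7,
                        reproduction = reproduction_spec("sort_biomass"))
run <- run_selection(cfg)
tail(run$aggregates, 3)

# archive and replay the best Adult of the last cycle
write_trajectory(run, "run01")
rec <- run$records[nrow(run$records), ]
replay_community("run01", rec$cycle, rec$community)
```
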