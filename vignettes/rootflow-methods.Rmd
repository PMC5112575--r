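---
title: "Soil water flow with root uptake: model and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soil water flow with root uptake: model and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootflow)
```

## The model

rootflow integrates the one-dimensional Richards equation for vertical
water flow in a vegetated soil,

$$ c(h)\,\frac{\partial h}{\partial t}
   = \frac{\partial}{\partial z}\!\left[K \frac{\partial h}{\partial z}\right]
   - \frac{\partial K}{\partial z} - S(z, t), $$

where $h$ is pressure head (m, negative when unsaturated), $z$ is depth
(m, positive downward, surface at zero), $K(\theta)$ is hydraulic
conductivity (m/s), $c(h) = d\theta/dh$ is the soil water capacity, and
$S(z,t)$ (1/s) is the volumetric rate of root water extraction.  The sign
of the gravity term follows from the downward-positive axis: gravity head
decreases in the direction of increasing $z$.

The profile is discretized with **block-centered finite differences**:
state ($h$, $\theta$) lives at block centers $z_i = (i - \tfrac12)\Delta z$,
conductivities and Darcy fluxes at block edges.  Time integration is
backward (implicit) in $h$ with $K$ and $c$ frozen at the old time level,
which linearizes each step into one tridiagonal system

$$ A_i h^*_{i-1} + B_i h^*_i + C_i h^*_{i+1} = D_i, \qquad
   A_1 = C_{nz} = 0, $$

solved with the Thomas algorithm in $O(nz)$.  Root uptake enters the
right-hand side only: relative to the sink-free coefficients, each $D_i$
is shifted by $-S_{i,t}$ while $A_i$, $B_i$, $C_i$ are unchanged.  The
upper boundary is either a prescribed surface flux $J(0,t)$ or a
prescribed surface head $h(0,t)$ (ghost spacing one full $\Delta z$, so
the surface-head term enters as $K_{1/2}\,h(0,t)/\Delta z^2$); the lower
boundary is a unit hydraulic gradient, i.e. gravity drainage with bottom
flux equal to the conductivity of the deepest block.

### The trial/accept flux-update scheme

Saturation breaks the head-based update (there $c = 0$ and $\theta$
carries no information), so each step uses a non-iterative trial/accept
scheme:

1. Solve the tridiagonal system with old-time $K$ and $c$, with the
   surface flux *withheld* from the pass, giving trial heads `HSTAR`.
   Re-evaluate conductivities at `HSTAR`, form interface fluxes (now
   including the withheld surface flux at the top edge), and compute a
   trial water content `THETA` from the conservative update
   $\theta^*_i = \theta_{i,t} - \Delta t\,(J_{i+1/2} - J_{i-1/2})/\Delta z
   - \Delta t\, S_{i,t}$.
2. Accept `THETA` in a block only if the block and its immediate
   neighbours are unsaturated; the new head is then read from the
   retention curve, keeping $h$ and $\theta$ consistent.
3. Otherwise reject `THETA`, take `HSTAR` as the new head and recompute
   $\theta$ from the retention curve, which caps water content at
   saturation.

The conservative update telescopes, so over any period the storage change
equals boundary fluxes minus extraction exactly for accepted blocks; the
ledger statistic `PCTDIF = (BIGI - WADD)/WADD * 100` reports the residual
closure error (BIGI is the gross infiltration recovered from storage
change plus drainage, transpiration and evaporation; WADD the rain
applied).  Rejected (saturated) steps are the only source of imbalance;
with forcing below the saturated conductivity the closure error of a
full-season run is at rounding level.

Boundary cases in the neighbour rule are resolved conservatively: block
1's upper neighbour is the surface, treated as saturated only under a
ponded head boundary; the bottom block's lower neighbour is itself.
A block counts as saturated when $\theta \ge \theta_s - 10^{-9}$, a
float-safe version of the binary test.

### Hydraulic property models

Two forms are supported per layer, dispatched through a common interface
(`theta_of_h()`, `h_of_theta()`, `K_of_theta()`, `water_capacity()`):

* **van Genuchten–Mualem** closed form ($\theta_r$, $\theta_s$, $\alpha$,
  $n$, $m = 1 - 1/n$, $K_s$), the default for synthetic work because its
  derivatives are smooth and exactly invertible;
* **tabulated** curves, piecewise linear in $h$–$\theta$ and $\theta$–$K$
  with flat extrapolation beyond the end nodes, matching the lineage of
  workflows that read measured retention tables.  The capacity is the
  active segment slope and zero outside the table and at saturation.

Internode conductivity is the arithmetic mean of the two adjacent block
values by default (`kmean = "geometric"` is available for sensitivity
checks); the literature this scheme descends from does not fix the rule,
and arithmetic averaging is that lineage's convention.

### Time stepping

The base step is a user-set constant (default 60 s) with automatic
halving and recovery: a step that produces non-finite values or water
content below residual is retried at half the step, and the step relaxes
back to the base after success.  Daily forcing is held constant within
the day.  This suits the old-time-$K$ linearization, which needs small
steps rather than iteration.  There is no convergence loop by design —
the scheme is deliberately non-iterative, and the refinement test
(halving $\Delta z$ and $\Delta t$ moves cumulative infiltration by
under 2%) plus the mass-balance audit stand in for an error estimator.

## Root water uptake

The sink is assembled per day from the potential transpiration `Tp`
delivered by the canopy partition (below) and dispatched on the model
selector `ICPS`:

* **ICPS = 1** — power-law root distribution with shape factor $\beta$:
  $S_i = \alpha(h_i)\,T_p\,(\beta + 1)(1 - z_i/L_t)^\beta /
  (86400000\, L_t)$ for $z_i \le L_t$.  The density integrates to one
  over the root zone, so unstressed uptake equals `Tp` up to quadrature
  error (below 1% at $\Delta z \le L/20$).  The factor 86 400 000
  converts mm/day to 1/s (86 400 s/day times 1000 mm/m).
* **ICPS = 3** — cubic normalized root density
  $L_{nrd}(z_r) = R_1 + R_2 z_r + R_3 z_r^2 + R_4 z_r^3$ (defaults
  2.21, −3.72, 3.46, −1.87, fitted wheat values) with proportional
  allocation of `Tp` over the discrete density and block-wise stress
  reduction — no compensation, so stressed blocks simply lose their
  share.  The density is floored at zero for user-supplied coefficients
  that dip negative; the allocation formula is this package's
  construction (mirroring the ICPS = 1 structure), since only the density
  itself is inherited.
* **ICPS = 2** — compensated uptake,
  $S_i = \alpha_i^2 L_{nrd,i}^\lambda T_p / (\Delta z_i \sum_j \alpha_j
  L_{nrd,j}^\lambda)$: demand lost in stressed blocks is shifted to wet
  ones.  Total uptake is $T_p \sum \alpha^2 L^\lambda / \sum \alpha
  L^\lambda$, which equals $a\,T_p$ under uniform stress $a$ and exactly
  $T_p$ for binary stress with at least one wet block — the compensation
  signature the test suite asserts against a direct-summation oracle.
  $\lambda \in [0.01, 2]$ is enforced at configuration time.  Full
  stress (all $\alpha = 0$) yields a zero profile flagged in
  diagnostics, not an error.

Stress is the Feddes trapezoid $\alpha(h)$: zero at and above the
anaerobiosis point $h_1$, optimal on $[h_3, h_2]$, zero at and below the
wilting point $h_4$.  Only $h_3$ and $h_4$ drive the experiments this
package targets; $h_1 = -0.1$ m and $h_2 = -0.25$ m are conventional
defaults, exposed in the configuration.  $h_4$ defaults to −150 m (a
wilting-point convention).  The **ending potential** $h_3$ is
transpiration-dependent: linear between $(T_{p1}, h_{31}) = (1\,\text{mm/day},
h_{31})$ and $(T_{p2}, h_{32}) = (5\,\text{mm/day}, h_{32})$, clamped to the
endpoints outside that range (the raw line is unbounded and would cross
$h_2$ or $h_4$ at extreme rates).  Three option sets are built in,
selected by `IHTH`: $(-11, -5)$, $(-14, -8)$ and $(-16, -10)$ m.

Root depth grows linearly from a seed depth `l0` (default one block — a
positive floor keeping the density well-defined) at Julian day `JTHAW`
to `zr_max` at `JMATUR`; the growth function between those dates is not
prescribed by the sources this model follows, and linear is the simplest
defensible choice.

## Surface forcing

Daily potential ET is split by Beer's law,
$T_p = ET_0 (1 - e^{-k\,\mathrm{LAI}})$, $E_p = ET_0 - T_p$ (extinction
coefficient $k = 0.5$ by default) — the partition formula is this
package's documented substitute, since the workflow it reproduces lists
LAI as an input without printing one.  Actual evaporation is limited
each sub-step by the Darcy exfiltration capacity of the surface block
toward an air-dry surface head (default −1000 m, half-block spacing),
and the net surface flux $(\text{rain} - E_a)/86400000$ m/s feeds the
flux upper boundary.  Air temperature and relative humidity are read and
carried for file fidelity but unused by the default physics.

## Parameter search

`run_search()` runs one independent simulation per lattice point over
$(\beta, Z_r^{max})$ — the default lattice is 16 $\beta$ values from 0.5
step 0.25 and 22 depths from 0.75 m step 0.05 m, 352 runs — and scores
each against measured water content with the **average relative
discrepancy**, the pooled mean of $|\theta_{sim} -
\theta_{obs}|/\theta_{obs}$ over all (day, depth) observations.  Pooling
(rather than averaging per day first) is this package's reading of
"average"; depths match to the nearest block center and days match
exactly.  Cells are pure functions of their inputs, so lattice order is
irrelevant and failures are recorded as `NA` sentinels with diagnostics
instead of aborting the sweep.  Seven summary grids (ARD and the ledger
components) are written by `write_outputs()`.

## The synthetic scenario generator

`make_scenario()` builds a fully self-contained study: a loam-like van
Genuchten soil ($\theta_r = 0.05$, $\theta_s = 0.45$, $\alpha = 2$ 1/m,
$n = 1.8$, $K_s = 10^{-6}$ m/s — fixture conventions, not field data), a
111-day growing-season weather series (day 134–244) with seeded
exponential rain pulses capped at 40 mm/day (below the 86.4 mm/day
saturated conductivity, so ponding rejection does not mask the
water-balance audit), a seasonal ET curve, an LAI ramp tied to the root
growth calendar, and a uniform initial profile at $h = -0.5$ m.  The
true root parameters default to $\beta = 2$, $Z_r^{max} = 1$ m, both on
the default search lattice.  Observations emulate daily-logging
moisture sensors: every day of the window at eight depths, with
optional seeded multiplicative noise.  Everything is deterministic given
the seed, and the generator restores the caller's RNG state.

What the generator does *not* emulate: layered field heterogeneity,
hysteresis, preferential flow, measurement bias, interception, or gaps
in sensor records.  Passing recovery tests therefore demonstrate the
correctness and identifiability of the machinery under the model's own
assumptions, not performance on field data.

## Problem sizes and numerical choices

The package's standard experiments use: the full scenario at
$\Delta z = 0.05$ m ($nz = 40$) and $\Delta t = 60$ s for the
mass-balance audit; the parameter-recovery study at the reduced
resolution $\Delta z = 0.1$ m, $\Delta t = 600$ s on an 8×8 sub-lattice
containing the truth, with 20 noise replicates at 2% — chosen so the
full study remains a desk-scale computation while the lattice step
(0.25 in $\beta$, 0.05 m in $Z_r$) still separates neighbouring cells.
Tie-breaks in the argmin take the first minimum in column-major order;
degenerate inputs (all-zero density weights, non-positive rooting depth,
out-of-range water contents) raise typed errors naming the offending
layer or block.

## Known limitations

* The old-time-$K$ linearization is first-order in time and needs small
  steps near sharp wetting fronts; no Picard/Newton iteration is
  provided, by design.
* Water rejected at a ponded surface is discarded rather than stored as
  a pond; `PCTDIF` makes the loss visible.
* Uptake compensation acts within a day's sink profile only; there is no
  plant water storage carrying deficit across days.
* One-dimensional vertical flow only: no macropores, vapor flow,
  freezing, osmotic stress, or root hydraulic architecture.

## A minimal session

```{r example, eval = FALSE}
sc <- make_scenario(scenario_spec(seed = 42))
run <- run_simulation(sc$profile, sc$grid, sc$init_theta, sc$weather,
                      sc$uptake)
run$ledger
obs <- synthesize_observations(run, days = sc$spec$obs_days,
                               depths = sc$spec$obs_depths, sd = 0.02,
                               seed = 1)
sr <- run_search(sc$profile, sc$grid, sc$init_theta, sc$weather, obs,
                 search_grid(), sc$uptake)
sr$argmin
```
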