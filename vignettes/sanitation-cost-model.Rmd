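---
title: "Modelling sanitation supply, walking exposure and assault cost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sanitation supply, walking exposure and assault cost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sanicost)
```

## The model and its assumptions

`sanicost` formalizes a simple causal chain in a dense urban township
where most residents rely on shared outdoor chemical toilets: fewer
toilets mean longer walks, longer walks mean more time exposed on foot,
and exposure time converts into expected sexual assaults at a constant
hazard. The model rests on four explicit assumptions:

1. **Random facility placement.** Toilet clusters are distributed
   uniformly at random over the settled area. For clusters of size $g$
   over area $A$, location density is $\lambda = t/(gA)$ and the mean
   distance from a uniform point to the nearest location is the
   stationary nearest-neighbor value $1/(2\sqrt{\lambda})$, so the mean
   round trip is $d(t) = \sqrt{gA/t}$.
2. **Exposure is travel time.** Risk accrues only while walking to or
   from a toilet — not while queueing or at the facility — at
   $e(t) = v \, d(t) / w$ hours per woman per day for $v$ round trips at
   speed $w$.
3. **Constant hazard.** Assaults arrive at a fixed rate $r$ per
   woman-exposure-hour, unchanged by the intervention itself (no
   displacement of perpetrators, no induced demand for trips), and
   constant across times of day.
4. **Static demography.** The female population is reconstructed from
   the toilet stock via the persons-per-toilet chain (toilets × families
   per toilet × household size × female share) and does not respond to
   the intervention.

Calibration anchors the chain at the observed baseline $t_0$: the
adjusted incidence $A_0$ (reported assaults scaled up for
under-reporting and restricted to the outdoor, en-route share) must be
reproduced, giving $r = A_0 / E(t_0)$ with $E(t)$ the annual
woman-exposure-hours. Because $E(t) \propto 1/\sqrt{t}$, expected
assaults follow $k/\sqrt{t}$ with $k = A_0\sqrt{t_0}$. The composite
social cost $C(t) = c\,t + s\,k/\sqrt{t}$ is strictly convex for
positive $c$, $s$, $k$ and minimized at $t^* = (s k / 2c)^{2/3}$.

```{r fit}
m <- sanitation_model(scenario_params())
m
optimal_toilets(m)
```

## Parameters that matter

All inputs live in `scenario_params()`; the defaults are the documented
base case. The influential ones, with units and why:

* `reported_assaults_per_year` (635/yr), `pct_reported` (0.15),
  `pct_outdoors` (0.30), `pct_enroute` (0.50) — the incidence adjustment.
  `A0 = reported × outdoors × enroute / reported-fraction`; at the
  defaults the outdoor and en-route shares multiply to exactly the
  reporting fraction, so $A_0 = 635$. The reporting fraction enters as a
  divisor and is the single most influential parameter.
* `trips_per_day` (6 round trips/woman/day) and `walk_speed_kph` (5 km/h)
  — convert distance to exposure time.
* `cluster_size` (7 toilets/location) — co-location is a pure cost on
  access: at a fixed stock, distance scales as $\sqrt{g}$.
* `base_roundtrip_m` (210 m) — the geometric anchor at the baseline
  stock of 5600 toilets; see below.
* `toilet_cost_rand` (R10,315/toilet/yr at 9.9 rand/USD, so $1041.92)
  and `assault_cost_usd` ($53,000/assault, a US estimate scaled by the
  GDP-per-capita ratio) — the two sides of the cost trade-off. Their
  ratio alone fixes $t^*$ (homogeneity of degree zero).

**The geometric anchor.** The effective settled area could in principle
be measured from census GIS layers, but the model only consumes it
through the baseline round-trip distance. We therefore treat
`base_roundtrip_m = 210` as primary and derive
`effective_area_km2 = (t0/g)·(d0/1000)² = 35.28` km², which is
consistent with the township's extent; supplying the area instead
derives the distance, and supplying both is accepted only when they
satisfy the distance law to 1e-9 relative.

## Sensitivity analysis and its propagation semantics

`tornado()` varies one parameter at a time over its documented range;
`psa()` draws all nine independently from uniform distributions (chosen
deliberately over shaped distributions — the bounds are defensible, the
shapes are not) and reports the fraction of draws whose optimum exceeds
the baseline stock.

One design choice here is genuinely open and consequential: what is held
fixed when a parameter moves? If the hazard $r$ were re-derived from
each draw's own behavioural values, trips per day, walking speed and
cluster size would cancel out of $t^*$ identically and carry zero
sensitivity — contradicting their observed influence. We therefore
re-derive only the incidence side per draw ($A_0$, hence $r$ against
*base-case* exposure) and push the behavioural and geometric draws
through the forward exposure model. Under these semantics the optimum is
multiplicatively separable,
$t^*(\theta) = t^*_{\mathrm{base}} \prod_i f_i(\theta_i)^{2/3}$,
a closed form the test suite verifies against the full pipeline at 1e-9
relative. A corollary worth stating plainly: at the low end of the trip
range (2 trips/day) the factor $(2/6)^{2/3}$ pulls the optimum to about
5455 toilets, roughly 2.6% *below* the baseline stock, so the summary
"every one-way excursion still favours expansion" holds for eight of the
nine parameters but not, strictly, for trip frequency.

```{r tornado}
head(tornado(m), 3)
psa(m, n_draws = 5000, seed = 1)
```

Draws are consumed parameter-by-parameter in tabulated row order from
one seeded generator, so any `(seed, n_draws, ranges)` triple is
bit-reproducible; tornado ties are broken by the same row order.

## The synthetic spatial layer: what it emulates, what it does not

`generate_sals()` emulates a small-area census layer as a rectangle
tiled by square cells (583 cells for the default township) with
populations proportional to area perturbed by a seeded log-normal
spread; `allocate_clusters()` apportions cluster locations to cells by
population (largest-remainder rule, ties by cell id) and places them
uniformly within cells; `simulate_mean_distance()` samples residents
population-proportionally and measures Euclidean distance to the nearest
location anywhere in the region.

This validates the distance law the analytic model assumes, and the
validation has teeth in both directions. In `"torus"` mode with all
locations placed uniformly over one cell, the simulated mean matches
$1/(2\sqrt{\lambda})$ to well under 1%. But two realistic departures are
measurable: hard region boundaries lengthen walks (bounded mode
exceeds torus mode), and per-cell apportionment *stratifies* the
placement — more regular than a Poisson pattern — shortening mean
distance by several percent at the default geometry. Real data depart
further in ways the simulator does not model: street-network detours
(walks are longer than Euclidean), non-random siting, and facility
disrepair. All of these push in the direction of more exposure per
toilet, so the analytic optimum is conservative. Passing spatial tests
therefore show internal consistency of the $1/\sqrt{t}$ law, not
field-measured accuracy of the 210 m anchor.

## Numerical choices

* **Continuous toilet counts.** $t$ is a positive real throughout;
  display rounding (toilets to the nearest 100, locations to the nearest
  10, costs to the nearest million USD, assaults and meters to integers,
  percent changes to the nearest 10 points) is applied only in
  `base_case_table()` and never feeds back into computation. Two
  published display cells are not reproducible under this (or any
  single) rounding rule: the base-case total renders 39 (the published
  40 is the sum of the two already-rounded component cells, 6 + 34, while
  the unrounded total is 39.49), and the optimal round trip renders 148
  (unrounded 147.53). The unrounded companions are always attached.
* **Optimization.** The closed form is exact; `optimal_toilets()`
  additionally runs a bounded golden-section search on $[1, 100\,t^*]$
  and warns beyond 0.1% disagreement. The cost-neutral bound uses
  bisection on the increasing branch to 1e-9 relative (monotonicity
  makes this robust where derivative methods need no safeguarding).
* **Degenerate inputs** are hard errors, not clamps: a zero reporting
  fraction, zero baseline exposure (e.g. zero trips) and toilet counts
  below 1 all stop with a message. A zero assault cost degrades the
  optimum to the domain boundary with an explicit warning.
* **Problem sizes.** The shipped checks use 5000 probabilistic draws,
  convolution oracles on ~500-atom grids, and spatial runs of 10^5–10^6
  resident samples averaged over 8–10 independent layouts — the layout
  average matters because a single realization's conditional mean varies
  by ±1–2% around the ensemble value at a few hundred locations.

## Known limitations

The model is a static, spatially homogeneous approximation: one hazard
for all hours and places, exposure restricted to travel time, no
behavioural response by perpetrators or by women, no within-township
heterogeneity in calibration (the synthetic layer varies density, but
$r$ and $k$ are global). The published hazard constant differs by ~4%
from the one implied by the persons-per-toilet chain (3.53e-5 vs
3.39e-5 per exposure-hour) — consistent with the original calibration
using census totals rather than the chain — and the published $k$
(47,485) differs by 0.07% from $635\sqrt{5600}$; the package derives
both from first principles and documents the tolerances in its tests.
Costs are annual, undiscounted and at a fixed exchange rate; co-benefits
of sanitation (notably waterborne-disease reduction) are ignored, which
again makes the optimum conservative.
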