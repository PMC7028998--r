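---
title: "Energy-budget assembly of seasonal bird distributions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-budget assembly of seasonal bird distributions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avisim)
```

## The model

`avisim` assembles a virtual global avifauna by greedy optimisation of an
annual energy budget. The world is an equal-area hexagonal grid; each cell
carries an energy supply for each of two seasons, northern summer (NS,
May–August) and northern winter (NW, November–February), derived from net
primary productivity:

$$E_{S,j} = \mu \,\log_{10}(\mathrm{NPP}_j + 1),$$

with negative NPP clamped to zero and ice-covered cells uninhabitable
($E_S = 0$). A virtual species is an ordered pair of *range options* — one
occupied in NS, one in NW — and is a **resident** when the two coincide,
a **migrant** otherwise.

Range options are fixed-size contiguous cell sets grown by a
climate-constrained spreading-dye process: a seed cell is drawn with
probability proportional to $1/(1+S_h)$ (where $S_h$ is the number of
species already occupying cell $h$), two neighbours of the seed are added,
and then each iteration adds 25% (rounded up) of the current frontier,
selected without replacement with weights $2(d+1)^{-x}$, where $d$ is the
Euclidean distance in a z-scored climatic space (mean annual temperature;
log10 annual precipitation) between the frontier cell and the running
climatic optimum — the mean climate of the cells already occupied. A
frontier cell adjacent to several occupied cells accumulates the weight
once per occupied neighbour. The final batch is truncated to the exact
target size, dropping lowest-weight cells first. Defaults: 400 options of
131 cells in the Western Hemisphere (WH, west of 30°W) and 600 options of
180 cells in the Eastern Hemisphere, and $x = 30$.

Each simulation step evaluates every ordered same-hemisphere pair of
options against the current energy field and adds the pair with maximal
year-round production

$$E_\mathrm{prod} = \beta\,(E_A^{(NS)} + E_A^{(NW)})
  - 2\,(BE_U + \alpha\, d_m),$$

where $E_A^{(s)}$ is the mean energy available over the season-$s$ range,
$\beta$ is the slope of the type-I functional response (assimilation
$=\beta E_A$), $BE_U = 1$ is the basal energy use per season (the model's
energy unit), $d_m$ the great-circle distance between the two range
centroids (km), and $\alpha$ the per-km migration cost. Breeding is
assigned to the season with the larger per-season production; ties break
to the season with more energy available, then to NS. The new species then
depletes each cell of each seasonal range by the fraction $\beta$ of that
cell's current availability (a resident, or an overlap cell of a migrant,
is depleted in both seasons). The hemisphere saturates when the best
candidate's $E_\mathrm{prod}$ is no longer positive; an alternative stop
rule (`assim_below_beu`: year-round assimilation below $BE_U$) is
available because the two are algebraically different
($E_\mathrm{prod}\le 0 \iff E_\mathrm{assim} \le 2(BE_U + \alpha d_m)$)
— the production rule is the default and saturates no later than the
assimilation rule admits.

Because depletion only ever lowers availability, every candidate's fitness
is non-increasing over steps, the best-candidate series is monotone, and
the loop provably terminates; the test suite asserts both, plus exact
agreement of each greedy selection with an exhaustive brute-force scan on
toy worlds.

## The migration-cost coefficient

$\alpha$ is derived from three allometries (mass $M$ in g): flight power
$F_W = 0.257\,M^{0.763}$ W, cruising speed $F_S = 6.4773\,M^{0.13}$ m/s,
and basal metabolic rate $\mathrm{BMR} = 6.7141\,M^{0.6452}$ mlO₂/h,
converted at 172 mlO₂/h per W and integrated over one 182-day season
(15,724,800 s) to give the seasonal basal energy
$\mathrm{BMR}_S \approx 6.15\times 10^5 M^{0.6452}$ J. Then

$$\alpha = \frac{1000\, F_W}{F_S\, \mathrm{BMR}_S}
  \approx 6.45\times10^{-5}\ \mathrm{km}^{-1},$$

with a residual mass exponent of $-0.0122$, so $\alpha$ is treated as
mass-free and all virtual species are functionally equivalent. Both the
rounded coefficient ($6.15\times10^5$, giving the conventional
$6.45\times10^{-5}$) and the exact conversion chain ($6.138\times10^5$,
giving $6.46\times10^{-5}$) are exposed; the rounded value is the package
default so that downstream numbers (e.g. a cost of ~6.5% of yearly basal
use per 1000 km) reproduce exactly. `energetics_table()` prints the whole
derivation.

## The grid

The grid is the vertex set of a Class I geodesic subdivision of the
icosahedron at frequency $n$: $10n^2+2$ cells, all with six neighbours
except the twelve icosahedral vertices with five. Adjacency comes from the
subdivision triangulation, which stitches exactly across icosahedron
faces. Cell areas follow the equal-area convention of icosahedral discrete
global grids — every hexagonal cell has the same area and pentagons carry
5/6 of it — rather than per-cell spherical-polygon integrals of this
particular construction, whose Voronoi areas wobble with gnomonic
distortion; the convention is exact for the grid family the simulator
assumes and keeps range areas strictly proportional to cell counts.
`hex_grid()` picks $n$ from a target mean cell area; the default
23,320 km² gives $n = 47$ (22,092 cells, ~163 km between adjacent
centres), at which a 131-cell range covers ≈3.0 million km² and a 180-cell
range ≈4.2 million km². An aperture-3 hierarchy ($10\cdot3^r+2$ cells)
would hit 21,872 cells instead; the Class I family was chosen because a
single, simply-stitched construction serves both the default resolution
and the much coarser grids used for testing, at a ~1% cost in the
reproduced range areas.

## The synthetic planet

`planet_spec()`/`make_planet()` generate self-contained test planets with
the structure the simulator assumes: an annual-mean temperature falling
quadratically from 27 °C at the equator by 60 °C towards the poles, a
seasonal half-amplitude growing linearly to 30 °C at the poles
(anti-phased between hemispheres, peaks in July/January), a precipitation
profile with wet tropics, dry subtropics and moderately wet temperate
belts with a modest summer wet season, Gaussian monthly noise, and a
polar ice cap. These values mirror observed Earth gradients
(annual means of ≈27 °C at the equator and ≈−30 °C at the poles;
continental mid-latitude half-amplitudes of 10–25 °C).

Monthly NPP is the minimum of a logistic temperature limit and a
saturating moisture limit with Miami-model constants
($A = 3000$ gC m⁻² yr⁻¹, $a = 1.315$, $b = 0.119$,
$c = 6.64\times10^{-4}$ per mm yr⁻¹, the moisture term seeing the
annualised rate $12P_\mathrm{month}$), divided by 12, and multiplied by a
freezing gate $\mathrm{plogis}(T/2)$. The gate is essential: the Miami
form was fitted to *annual* climate, and applied to monthly values it
leaves substantial productivity in sub-freezing months, whereas monthly
output of process vegetation models drops to ~0 when frozen. Without it
the log-compressed supply contrast between tropical and temperate winters
is too weak to ever repay a migration at $\alpha = 6.45\times10^{-5}$,
and the simulated avifauna degenerates to residents only; with it the
default planet supports the qualitative structure the model is built to
produce — tropical residents plus temperate-breeding migrants — which the
test suite asserts. The generator emits NPP on the gC m⁻² month⁻¹ scale
(monthly values up to ≈200) so that the default supply scaling $\mu = 65$
remains meaningful.

What the planet does *not* emulate: continents and oceans (every non-ice
cell is habitable), orography, realistic storm tracks, or any quantitative
match to a particular paleoclimate reconstruction. Passing tests on these
planets therefore demonstrate the mechanics and limit behaviours of the
model, not predictive skill on real climate fields, which must be supplied
as per-hexagon CSV tables.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `beta` | 0.012 | – | type-I response slope; the one free parameter, calibrated by `beta_scan()` over 0.003–0.035 (step 0.001) |
| `alpha` | 6.45e-5 | per km | migration cost; from the flight allometries |
| `mu` | 65 | energy units | NPP-to-supply scaling (carrying capacity) |
| `be_u` | 1 | energy units | basal energy use per season (fixed scale) |
| `x` | 30 | – | climatic-constraint exponent of range growth |
| `n_options` | 400 WH / 600 EH | – | candidate ranges per hemisphere per slice |
| `range_sizes` | 131 WH / 180 EH | cells | median bird range sizes at the default grid |

Below `beta` ≈ 0.003 (on a world of the reference supply scale) no
species is viable; large `beta` makes first-species assimilation
implausibly large. `sensitivity_scan()` varies `alpha`, `mu`, the range
sizes or `x` with everything else fixed; richness rises with `mu`
(carrying capacity) and falls with range size (fewer species fit), and
the migrant fraction falls as `alpha` rises — the trend signs the
acceptance tests check.

## Numerical and design choices

* **Depletion granularity.** The selected species consumes $\beta$ of
  each member cell's own availability per season, consistent with
  $E_\mathrm{assim} = \beta\,\mathrm{mean}(E_A)$ and guaranteeing
  $0 \le E_A \le E_S$ with no reallocation logic.
* **Candidate evaluation** uses the field as of the start of the step; no
  intra-step depletion.
* **Ordered pairs.** Candidates are all ordered (NS, NW) option pairs
  within a hemisphere (residents on the diagonal); season roles are part
  of the candidate, and breeding is then assigned to the more productive
  season, so no candidate is lost relative to enumerating unordered pairs
  under both roles.
* **Tie-breaks.** Argmax ties resolve to the lowest (breeding,
  non-breeding) option-id pair; breeding-season ties to the season with
  larger $E_A$, then NS. All randomness flows through named substreams of
  one master seed (`derive_seed()`), so runs are bit-reproducible and a
  scan point's randomness never shifts another's.
* **Degenerate climates.** A zero-variance climatic dimension is set to
  z = 0 with a classed warning: climatic distances in it vanish and
  growth proceeds on the remaining dimension.
* **Option generation order.** The option set is generated once per time
  slice before any species exists ($S_h = 0$ in the seeding law);
  `generate_option_set()` accepts an explicit `s_h` for mid-run
  regeneration if a different protocol is wanted. Stalled growths
  (frontier exhausted by ice or hemisphere edges) are re-seeded with a
  bounded retry budget.
* **Hemispheres** are simulated independently (ranges never span the
  30°W split) and merged for global metrics; "Americas"/"Old World" in
  outputs mean WH/EH. The −30° meridian itself belongs to EH.
* **Pattern scoring** uses unweighted per-cell Pearson correlations, with
  a migrant's overlap cells (present year-round) counting in neither
  migrant map by default (`overlap = "resident"` counts them as resident
  occurrences instead). Zero-variance patterns are excluded from the
  composite with a warning.
* **Per-slice standardisation.** The climatic space is z-scored per time
  slice over that slice's habitable cells (each world carries its own
  space); nothing is anchored to the present slice.

## Problem sizes

Tests and examples run on coarse planets — frequency 3–6 grids (92–362
cells) with 24/36 options of 10/14 cells — where a full assembly runs in
under a second and a sensitivity scan in a few seconds; the greedy-oracle
equivalence uses ≤100-cell worlds with ≤10 options so the exhaustive scan
stays trivially cheap. The default-resolution grid (22,092 cells) is
exercised for geometry and range-area checks. Full-scale multi-slice
reconstructions (hours of compute and external paleoclimate/NPP input)
are out of scope of the shipped tests; `simulate_timeseries()` runs the
same machinery on any list of worlds.

## Known limitations

* All species share one body-mass-free cost coefficient and one range
  size per hemisphere; there is no abundance structure, no within-season
  movement, and no between-slice memory.
* Migration cost is the geodesic between range centroids: seas,
  mountains, stopovers and winds are invisible to it.
* The synthetic planets contain no land/sea mask, so simulated richness
  fields are smoother than any real avifauna's.
* A grid re-read from CSV supports simulation but not polygon export
  (the triangulation is rebuilt only by `hex_grid_freq()`).
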