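---
title: "Modelling spatial contagion patterns with sirscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spatial contagion patterns with sirscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirscape)
```

## The model

`sirscape` simulates a generalized SIRS contagion on an `L x L` periodic
lattice of locations, each hosting a fixed sub-population of `P` residents
split into susceptible (`S`), affected/infected (`I`) and recovered (`R`)
compartments. Three rates drive the compartmental dynamics: transmission
`beta` (per interaction), recovery `gamma`, and susceptibility acquisition
`zeta` — the rate at which recovered individuals lose immunity. `zeta = 0`
is the SIR limit (permanent immunity, the contagion dies out); `zeta = Inf`
is the SIS limit (recovery returns individuals straight to `S`), which the
package integrates exactly via `run_sis_limit()` rather than through a
stiff large-`zeta` system.

What makes the dynamics spatial is mobility. Every location can reach five
destinations at unit cost: itself and its four lattice neighbours (torus
wrap-around). Each destination `j` offers a *benefit* `b_j = (P_j - I_j) /
P_j`, the fraction of its population not currently affected. The
destination distributions of susceptible and affected individuals are the
maximum-entropy (least biased) distributions compatible with constraints on
the mean destination benefit and mean mobility cost; their closed form is a
softmax, `phi_ij ∝ exp(alpha * b_j - omega * c_ij)`, with one Lagrange
multiplier per compartment:

* `alpha_S` — *risk aversion* of susceptibles. Positive values steer them
  toward less-affected destinations; negative values are risk-seeking.
* `alpha_I` — *adaptive responsiveness* of the affected. Positive values
  drive them away from affected locations (flight); negative values mean
  acceptance of, or attraction to, the contagion.
* `omega` — cost sensitivity. On the equal-cost lattice the cost term is
  constant within each row of the flow matrix and cancels in the softmax
  normalization, so `omega` is unidentifiable and irrelevant here (a tested
  invariant); it is kept for future heterogeneous cost matrices, and
  defaults to 1.

The sign quadrants of the (`alpha_I`, `alpha_S`) plane map onto four
contagion types (see `quadrant_of()`): epidemic-like flight (+,+),
polarization/segregation (−,+), social-myth spreading (−,−) and
socio-economic turbulence (+,−). A zero on either axis is reported as
`"boundary"` rather than forced into a quadrant.

Mobility is *fast* relative to the contagion: flows re-equilibrate to the
current infection field at the start of every integration step, with no
relaxation dynamics of their own. New transmissions to residents of `i`
occur at every reachable mixing location `j`, in proportion to the affected
share of the mixing population there; the mixing population sums only
susceptible and affected inflows, because recovered individuals do not
contribute to transmission. `network_derivatives()` is the reference
implementation of this vector field; the integrator in `run_simulation()`
is an equivalent compiled loop, and a test pins one compiled step to the
R-level composition of `location_benefit()`, `compute_flows()` and
`network_derivatives()`.

## Default study conditions

The package defaults in `sim_config()` are the reference conditions used by
every sweep and test: `L = 40`, `beta = 10`, `gamma = 5`, explicit Euler
with `dt = 0.001` over `n_steps = 10000` (total simulated time 10), uniform
sub-populations `P = 100`, and initial infections drawn independently per
location as `Uniform(0, 0.05) * P`. The sub-population scale is arbitrary:
the dynamics are invariant under a global rescaling of `P` (a tested
property), so only a reference value is needed. Explicit Euler with the
small reference step is used deliberately — a higher-order adaptive scheme
would be more accurate per step but would not follow the same discrete
trajectories that define the study conditions. Compartments that undershoot
zero by less than `1e-9 * P` (round-off) are clamped; larger undershoot
raises a stability error advising a smaller `dt`.

```{r, eval = FALSE}
sim <- run_simulation(sim_config(alpha_I = 25, alpha_S = -25, zeta = 100,
                                 seed = 1))
glance(sim)
autoplot(sim)
```

## Pattern analysis

The final infection field is binarized: a cell is occupied when its value
strictly exceeds the lattice mean. Occupied cells are grouped into clusters
under 8-connectivity (lateral + diagonal adjacency), wrapping at the edges
for simulated lattices (the model is a torus) and not wrapping for
geographic grids. The percolation order parameter is the *site-weighted*
mean normalized cluster size,
`ACS = sum(r^2) / (L^2 * sum(r))` over cluster sizes `r` — the wording "a
site belongs to a cluster of size r" dictates weighting by sites, and the
largest (possibly percolating) cluster is included because that sharpens
the transitions. A cluster-weighted variant exists behind
`weighting = "cluster"` but is not the default.

ACS bands separate pattern types: undefined (no occupied cell) is the
*uniform* class; `(0, 0.04]` *spots*; `(0.04, 0.4]` *labyrinth*;
`(0.4, 1]` *connected* — the latter covering both *gaps* (a connected sea
with holes) and *chequerboard* patterns, which the staggered magnetization
`m_s` tells apart (`m_s = 1` for a perfect chequerboard, `~0` for gaps;
`m_s > 0.5` is a reasonable chequerboard call, reported alongside and never
replacing the band label). Band boundaries are right-closed exactly as
stated: `0.04` is spots, `0.4` is labyrinth.

**A numerical choice worth knowing about.** When the two dispositions are
equal (and generally below the `alpha_I = alpha_S` diagonal at high
`zeta`), the infection field homogenizes. In exact arithmetic it would
become constant and binarize to an empty grid; in floating point it
converges to a relative spread of about `1e-12`–`1e-14` and never becomes
exactly constant, so a literal strict threshold would binarize round-off
noise into a spurious giant cluster. `binarize_above_mean()` therefore
treats a cell as occupied only when its excess over the mean exceeds
`rel_tol * |mean|`, with `rel_tol = 1e-9` — chosen from the observed
round-off scale and several orders of magnitude below the relative spread
of any genuinely patterned field we observe (`>= 1e-4`). Constant and
numerically-constant fields thus map to the uniform class.

## Phase diagrams and tipping points

`scan_alpha_plane()` runs the simulation over a grid of disposition values
at fixed `zeta` (default `-50..50` in steps of 5, giving an 11 × 11
sub-grid per sign quadrant including the zero edges) and returns a tibble
of per-point percolation summaries; `autoplot()` draws the band map.
Per-point seeds follow a deterministic schedule derived from the base seed
and the grid indices, so any execution order — or a parallel split —
reproduces the same diagram.

`sweep_zeta()` traces one configuration across a logarithmic `zeta` grid
(default `0.1 ... 1000`) with mean ± SD of the ACS over `n_runs`
independent initial conditions (default 10). `zeta = 0` is accepted as a
categorical SIR endpoint but excluded from log-scale analysis.
`detect_critical_zeta()` locates the tipping point as the geometric mean of
the adjacent grid values bracketing the largest `|d log ACS / d log zeta|`;
undefined ACS values enter at a floor of `1 / L^2` (the smallest resolvable
normalized cluster), so the emergence of a pattern out of the uniform
regime registers as a large jump. An exactly flat curve yields "no critical
point". The detector is invariant to rescaling the order parameter by a
positive constant.

### Representative configurations

The four contagion types are represented in the tests and the acceptance
script by configurations chosen from the quadrant structure and the
inequalities that separate pattern types (spots where risk aversion is
dominated by strongly negative responsiveness; labyrinth and gaps above the
anti-diagonal; chequerboard below the main diagonal):

| role | `alpha_I` | `alpha_S` | `zeta` | expected band |
|---|---|---|---|---|
| myth/polarization spots | −50 | 20 | 100 | spots (≤ 0.04) |
| turbulence chequerboard | 25 | −25 | 100 | connected (≥ 0.4), `m_s` high |
| epidemic labyrinth | 5 | 50 | 1000 | labyrinth (0.04–0.4) |
| polarization (tipping point) | −10 | 40 | sweep | critical `zeta` ≤ 3 |
| epidemic gaps (tipping point) | 10 | 45 | sweep | critical `zeta` ≤ 10 |

The epidemic-gaps representative was selected by three criteria that the
epidemic quadrant's gaps regime must satisfy: `alpha_S > alpha_I` within
the (+,+) quadrant, a connected-band/low-`m_s` (gaps, not chequerboard)
pattern in the SIS regime, and a proto-pattern emerging around `zeta ~ 1`.
Deeper-quadrant points such as (25, 45) remain numerically uniform until
`zeta > 10` and only pattern up near `zeta ~ 30`, so they represent a
later-onset regime rather than the canonical gaps phenomenology; (10, 45)
satisfies all three criteria, with its tipping point detected at
`sqrt(3) ~ 1.7`.

## The geospatial pipeline

The same order parameter can score real choropleth data. A polygon layer
(GeoJSON `FeatureCollection` with per-region `population` and `count`
properties, in planar coordinates) is read by `read_region_layer()`;
`rasterize_layer()` overlays an `n x n` grid (default 40) on the layer
bounding box and splits each region's count and population across cells in
proportion to region–cell overlap area (uniform areal weighting, computed
by exact rectangle clipping; mass is conserved to rounding). Cells with any
polygon overlap form the *reachability mask*; cells outside it (ocean,
out-of-study areas) are excluded from the binarization mean and can never
be occupied. `normalized_acs()` reports both the raw ACS (non-periodic
8-connectivity, normalized by `n^2`) and its value renormalized against the
"fully percolated" grid in which every reachable cell is occupied, so a
pattern filling the whole study region scores exactly 1 regardless of the
region's shape. `superimpose()` unions two binarized grids over the same
frame (an intersection rule is available), for mixed-mode analyses that
combine two datasets.

Two deliberate simplifications: the grid frame is the axis-aligned bounding
box in the layer's own planar coordinate system (no reprojection — inputs
must already be projected or locally near-planar), and interpolation is by
overlap area only (no dasymetric weighting). Published ACS values for real
administrative datasets are therefore reproducible only conditional on
matching the original grid frame; absolute comparisons should treat the
frame as part of the experiment.

```{r, eval = FALSE}
f <- system.file("extdata", "synthetic_regions.geojson", package = "sirscape")
layer <- read_region_layer(f)
score_region_layer(layer, n = 40)
```

## Synthetic data

Two generators make every stage testable without external data.
`make_pattern()` produces archetypal fields whose band membership is
provable by counting — e.g. eight isolated 2 × 2 blobs on a 40 × 40 grid
give `ACS = 4/1600 = 0.0025` (spots), and a perfect chequerboard joins each
colour class into one diagonal-connected cluster of 800 sites, giving
`ACS = 0.5` and `m_s = 1`. `make_region_layer()` partitions a bounding box
into rectangular regions by recursive random splits (a rectangular
partition satisfies the no-gap/no-overlap invariant exactly and keeps the
clipping arithmetic exact; generating-model realism is not the goal), draws
populations uniformly, and assigns Poisson event counts at a configurable
per-person rate, optionally boosted inside a hot-spot box. These layers
emulate the *schema* of administrative data — polygons, populations,
counts — not the statistical texture of any real dataset: passing tests
demonstrate correct redistribution, masking and scoring, not calibration to
any particular geography.

## Problem sizes used by the tests

Unit and property tests run on small lattices (5–16) with shortened
integrations, which exercise every code path; the acceptance-style checks
run the full reference conditions (40 × 40, 10^4 steps) with 5 seeds per
configuration and a 7-point `zeta` grid for the tipping-point bounds. The
complete four-quadrant phase diagram at 10 runs per point is provided as a
documented batch script (`scripts/phase_diagram_batch.R`) rather than a
test.

## Known limitations

* Explicit Euler with fixed `dt`: configurations far outside the reference
  parameter ranges may need a smaller step (the integrator detects and
  reports instability rather than silently clamping).
* No demographic stochasticity: randomness enters only through initial
  conditions, matching the deterministic-dynamics scope.
* Stationarity at the final time is not verified by default; the reported
  statistic is the final-time field. `snapshot_every` makes late-time
  drift checks easy if needed.
* The geo pipeline does not reproject coordinates and uses uniform areal
  weighting; both are part of the method definition here.
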