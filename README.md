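# sirscape

Pattern formation and tipping points in spatial contagion models.

`sirscape` is for researchers studying how contagions — epidemics, opinion
polarization, social-myth spreading, civil unrest and boom-and-bust
investment waves — organize themselves in space. It implements a
generalized SIRS (susceptible–infected–recovered–susceptible)
metapopulation model on an `L x L` periodic lattice in which population
mobility is not fixed but responds to the contagion itself: at every step,
susceptible and affected individuals redistribute over their reachable
destinations according to maximum-entropy flows

```
phi_ij ∝ exp(alpha * b_j − omega * c_ij),      b_j = (P_j − I_j) / P_j,
```

where `b_j` is the destination's benefit (its unaffected fraction), and the
Lagrange multipliers `alpha_S` (risk aversion of susceptibles) and
`alpha_I` (adaptive responsiveness of the affected) encode bounded risk
disposition. Their sign quadrants correspond to the four contagion types
above. The slow dynamics couple these fast flows to SIRS compartments with
transmission rate `beta`, recovery rate `gamma` and susceptibility
acquisition `zeta` (`zeta = 0` → SIR, `zeta → ∞` → SIS, integrated exactly
by `run_sis_limit()`):

```
dI_i/dt = −gamma I_i + beta S_i Σ_j phi^S_ij (Σ_k phi^I_kj I_k) / N̂_j
```

with `N̂_j` the mixing population at location `j` (susceptible plus
affected inflows). The resulting stationary infection fields form Turing-
like patterns — spots, labyrinths, gaps, chequerboards — which the package
quantifies by percolation analysis: binarize the field above its mean,
label clusters with 8-connectivity, and compute the site-weighted mean
normalized cluster size (ACS), largest cluster included. ACS bands
delimit the pattern types (undefined → uniform; ≤ 0.04 → spots; ≤ 0.4 →
labyrinth; ≤ 1 → connected), with the staggered magnetization separating
chequerboard from gaps within the connected band. Sweeps over
(`alpha_I`, `alpha_S`) produce phase diagrams; sweeps over `zeta` locate
tipping points as the largest log–log change of the ACS. A companion
geospatial pipeline redistributes polygon-level counts (e.g. incidence per
administrative area) onto a grid by overlap area and scores real
choropleth data on the same order parameter.

## Worked example

```r
library(sirscape)

# a social-myth/polarization configuration: strongly myth-seeking affected
# population (alpha_I = -50), risk-averse susceptibles (alpha_S = 20)
sim <- run_simulation(sim_config(alpha_I = -50, alpha_S = 20, zeta = 100,
                                 seed = 1))
glance(sim)
#> # A tibble: 1 × 11
#>   mode   zeta alpha_I alpha_S total_S total_I total_R infected_fraction
#>   <chr> <dbl>   <dbl>   <dbl>   <dbl>   <dbl>   <dbl>             <dbl>
#> 1 sirs    100     -50      20 153196.   6480.    324.            0.0405
#> # ℹ 3 more variables: acs <dbl>, m_s <dbl>, band <chr>

percolation_summary(final_field(sim))
#> # A tibble: 1 × 6
#>   n_occupied n_clusters   lcs     acs     m_s band
#>        <int>      <int> <int>   <dbl>   <dbl> <chr>
#> 1        479         63    31 0.00677 0.00375 spots
```

About 4% of the population is affected at the final time, and the
above-mean cells split into 63 isolated clusters (largest: 31 cells of
1600): an ACS of 0.0068 falls in the spots band, the signature of pocketed
contagion. `autoplot(sim)` draws the field;
`scan_alpha_plane()` / `sweep_zeta()` + `detect_critical_zeta()` map the
full phase structure, e.g.

```r
sw <- sweep_zeta(alpha_I = -10, alpha_S = 40,
                 zeta = c(0.1, 0.3, 1, 3, 10, 100, 1000),
                 config = sim_config(seed = 1), n_runs = 5, base_seed = 1)
detect_critical_zeta(sw)
#> <critical_zeta> zeta_c = 0.5477 (bracket 0.3..1, |dlogACS/dlogzeta| = 5.48)
```

— the polarization configuration's patterns emerge critically between
`zeta = 0.3` and `1`. A thin command-line front end (`exec/sirscape`)
exposes the same operations as subcommands (`simulate`, `scan`,
`zeta-sweep`, `classify`, `rasterize`, `superimpose`, `fixtures`).

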