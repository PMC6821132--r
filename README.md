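# clearkin

Clearance kinetics of developmental cell death, with the surrounding
quantification toolkit used in studies of retinal glial mosaics.

## The problem

Developing neural tissues routinely lose large fractions of a cell
population, yet histological snapshots show almost no dying cells,
because each corpse is visible only for a short **clearance time**
before a phagocyte removes it. This package is for developmental
biologists and biostatisticians who need to ask, quantitatively: *is
the death marker I can see frequent enough to explain the population
decline I can count?*

The core is the closed-form death-window model. With `S` the starting
count, `N_T` the final count, `n` the window length (days), `D` the
snapshot visibly-dying fraction, and `V` the clearance time (hours),
the expected per-day loss fraction is `d = D·24/V` and

```
N_T = S (1 − D·24/V)^n        ⇒        V = 24D / (1 − (N_T/S)^(1/n))
```

Around it sit:

* a stochastic death-and-clearance **simulator** with daily snapshot
  observation, for end-to-end estimator validation
  (`simulate_death_process()`, `recover_clearance_time()`);
* **stereology**: whole-retina totals from central/middle/peripheral
  field densities with 11%/33%/56% area weights
  (`weighted_mean_density()`, `total_count()`, `sample_fields()`);
* **spatial indices**: Voronoi domain regularity (`voronoi_regularity()`),
  engulfment classification (`classify_engulfment()`), lysosome index,
  network coverage, Li/triangle auto-thresholding, and
  enclosure-based debris localisation;
* seeded **generators** for retinal point patterns, repulsive vs random
  mosaics, and label-mask scenes with exact ground truth;
* typed CSV IO with provenance sidecars, and a thin CLI
  (`inst/cli/clearkin`) with subcommands `solve-v`, `predict-nt`,
  `project-loss`, `corpse-band`, `estimate-total`.

## Worked example

```r
library(clearkin)

tibble::tibble(
  scenario = c("RGC validation", "astrocyte apoptosis",
               "astrocyte engulfment"),
  s   = c(200000, 26987, 26987),
  n_t = c(117000, 6513, 6513),
  d   = c(0.005375, 0.000583, 0.00556),
  n   = c(10, 9, 9)
) |> solve_clearance()
#> # A tibble: 3 × 7
#>   scenario                  s    n_t        d     n v_hours v_minutes
#>   <chr>                 <dbl>  <dbl>    <dbl> <dbl>   <dbl>     <dbl>
#> 1 RGC validation       200000 117000 0.00538     10  2.47      148.
#> 2 astrocyte apoptosis   26987   6513 0.000583     9  0.0958      5.75
#> 3 astrocyte engulfment  26987   6513 0.00556      9  0.913      54.8
```

Read: the retinal-ganglion-cell decline (200,000 → 117,000 over 10
days) with a 0.54% pyknotic snapshot implies a 2.47 h clearance time —
squarely in the 1–3 h range reported for apoptotic neurons, validating
the model. The same decline in astrocytes (26,987 → 6,513 over 9 days)
with the observed 0.058% apoptotic fraction would require corpses to
vanish in under 6 minutes — implausible, so apoptosis cannot explain
the loss — whereas the 0.556% fully-enveloped fraction implies 54.8
minutes, consistent with measured microglial engulfment times.

Projecting losses and propagating uncertainty in `D`:

```r
proj <- loss_projection(S = 26987, D = 0.0003, V = 2.47, n = 9)
glance(proj)
#>       S      D     V     n per_day_loss final_count total_loss mean_daily_loss
#> 1 26987 0.0003  2.47     9      0.00291      26287.       700.            77.8

est <- visible_fraction_estimate(mean = 0.0003, ci_low = 0.0002,
                                 ci_high = 0.0006)
corpse_density_band(S = 26987, V = 2.47, n = 9, estimate = est,
                    k = 6, area = 10)
#>   bound      d cells_lost density
#> 1 low   0.0002       312.    31.2
#> 2 mid   0.0003       467.    46.7
#> 3 high  0.0006       922.    92.2
```

The band is the expected density of *uncleared* corpses after 6 days if
phagocytic clearance were absent (e.g. in microglia-deficient tissue) —
31–92 cells/mm², against well under 1 cell/mm² visible when clearance
operates.

See `vignettes/clearance-kinetics.Rmd` for the model assumptions, the
simulator design, and every numerical choice.

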