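# lakefcc

Satellite-driven assessment of how much fish a lake's primary production
can sustain, for quantitative fisheries ecologists and managers of
single-species (often restocked) lake fisheries.  The motivating system is
a large, oligotrophic high-altitude lake dominated by one zooplanktivorous
species, where field campaigns are sparse and ocean-colour archives are the
only long-term record of the food base.

The package chains five stages, each usable on its own:

1. **Scene QC** — per-pixel quality filters (nominal flag, straylight
   < 5 %, no ice), a unified minimum-extent lake mask, monthly composites
   requiring ≥ 5 valid days per cell, interior-gap temporal interpolation,
   matchup extraction (box median, ±12 h, box SD < 20 % of mean) and a
   type II (reduced major axis) chlorophyll correction.
2. **Primary production** — the Vertically Generalised Production Model:

   `PP = 0.66125 · Pbopt(T) · E0/(E0 + 4.1) · Zeu · Chl · Dirr` (mg C m⁻² day⁻¹)

   with the published polynomial-and-clamps `Pbopt(T)`, euphotic depth
   `Zeu = ln(100)/Kd(PAR)` capped at the lake depth, and astronomical
   daylength.
3. **Fish potential production** — the trophic chain
   `NetFPP = NetPP · aⁿ · (P/B)/E` (g m⁻² month⁻¹; baselines a = 0.10,
   n = 2, P/B = 30, E = 2.5 kJ/g), aggregated to lake-wide Gross Monthly
   and May–October Gross Annual FPP in tonnes.
4. **Stock and index** — survey biomass
   `FP = density · weight · volume · 10⁻⁶` t from acoustic transects and
   gill nets (`TS = 19.1·log10 L − 0.9·log10 f − 62` dB backs the synthetic
   surveys), and the carrying-capacity index `FCCI = FP / GrossAnnualFPP`
   with management thresholds (0.3 / 0.5 / 0.6 / 1.0), per-cell maps and
   restocking-zone recommendations.
5. **Uncertainty** — matchup validation metrics (ARE, CC, RMSE, EA) and
   Monte Carlo propagation of ±20 % uniform trophic-parameter variation
   into FPP and FCCI, with a batch convergence check.

A seeded synthetic-scene generator (shore-high/centre-low chlorophyll with
estuary hotspots, seasonal cycle, lognormal pixel noise, cloud gaps, and
surveys that integrate to a known true biomass) makes every stage testable
offline; a published 23-year annual FP/FPP series for Qinghai Lake ships as
package data for the management-scale examples.

## Worked example

Assess the bundled 2002–2024 series and propagate parameter uncertainty:

```r
library(lakefcc)
qs <- qinghai_lake_series()
a  <- fcci_assessment(qs$fp_t, qs$fpp_t, qs$year)
summary(a)
#> Lake-wide FCCI over 23 years: max 0.5825 in 2023; trend increasing
#>   years with FCCI > 0.3 (underutilised): 7
#>   years with FCCI > 0.5 (high_pressure): 2
#>   years with FCCI > 0.6 (benchmark): 0
#>   years with FCCI > 1.0 (max_sustainable): 0
#>   all years below the benchmark: restocking headroom remains

fcci_annual(127500, 244581, year = 2024)
#> FCCI 2024 = 0.5213 (FP 127500 t / FPP 244581 t) [high_pressure]
```

The stock grew fifty-fold over the record while the index stayed below the
0.6 benchmark in every year: the food base could still support further
restocking, with releases best directed at underutilised (FCCI < 0.3)
areas — see `fcci_map()` and `classify_zones()` for the spatial version.

Uncertainty in the trophic constants:

```r
mc <- run_monte_carlo(trophic_params(), qs$fp_t,
                      pp_series_from_fpp(qs$fpp_t, trophic_params()),
                      mc_config(iterations = 1000, seed = 1))
mc
#> Monte Carlo sensitivity: 1000 iterations, +/-20% uniform variation
#>   one-at-a-time FPP relative RMSE (%):
#>     a    23.18
#>     pb   11.85
#>     n    62.33
#>     E    12.56
#>   P(FCCI > 0.6): pooled 12.57%, worst year 48.70%
#>   convergence CV across batches: 1.4359% (stable: FALSE)
```

The linearly-entering P/B ratio shows the analytic `0.2/√3 ≈ 11.5 %` RMSE;
parameters entering through the exponent (`aⁿ`) are far more consequential.
With the parameters held at baseline the benchmark is never crossed.

A full synthetic end-to-end run (scenes → QC → PP → FPP → survey → index):

```r
run <- run_assessment(run_config(years = 2023:2024,
                                 scene = scene_config(grid_shape = c(20, 20), seed = 1)))
run$table      # year, fp_t, fpp_t, fcci, status
run$zones      # management zones + recommended release region
```

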