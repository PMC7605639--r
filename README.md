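# ecotone

Delimitation of the transition zone (ecotone) between two climate zones from
co-registered environmental rasters and the mapped occurrences of paired
indicator vegetation types — for biogeographers and spatial ecologists who
want a climate regionalization that treats the subtropical/temperate divide
as a *band*, not a line.

Where two climate zones meet, each indicator-vegetation pair (a subtropical
and a temperate conifer, paired oaks, paired broad-leaved species) places its
own boundary slightly differently; the band jointly swept by those boundaries
is the transition zone. The package estimates it in four steps:

1. **Covariate screening per pair** with the factor-detector q-statistic,

   *q* = 1 − (Σ<sub>h</sub> N<sub>h</sub> σ<sub>h</sub>²) / (N σ²),

   computed with population variances (so *q* = 1 − SSW/SST, the one-way
   ANOVA eta-squared) over the two vegetation classes as strata, with a
   seeded permutation significance test.
2. **Index-system selection**: covariates with *q* strictly above 0.3, top 4
   by *q*, ties broken by name.
3. **Zonation**: a binary soft-margin SVM (RBF kernel) on the labeled
   pixels' selected covariates predicts a wall-to-wall two-zone map per
   pair; the inter-zone boundary polylines are extracted along
   4-connectivity pixel edges.
4. **Composition, characterization, validation**: the per-column extreme
   crossings of all pairs' boundaries bound the transition band (width
   profile and mean width in map units); the resulting three-zone partition
   is characterized by zonal sampling and three-strata q-statistics, and
   validated against graded quadrat survey counts.

A synthetic-landscape generator with known boundary geometry, logistic
driver responses, autocorrelated nuisance fields, sparse observation and
simulated quadrat surveys makes the whole workflow testable against ground
truth without any external data. See the methods vignette
(`vignettes/transition-zone-delimitation.Rmd`) for the model, its
assumptions and the design choices.

## Worked example

```r
library(ecotone)
land <- generate_landscape(synthetic_truth(seed = 1))   # 200 x 200, 3 pairs
fit  <- ecotone_model(land$stack, land$occurrences, B = 199, seed = 1)
print(fit)
```

```
Transition-zone model (q-statistic screening + SVM zonation)
  pairs: I, II, III
  pair I    index system: meantem01, dem, pa, tadem (training accuracy 0.974)
  pair II   index system: pa, dem, tadem, meantem01 (training accuracy 0.994)
  pair III  index system: tadem, dem, pa, meantem01 (training accuracy 0.992)
  transition band: mean width 29.04 map units
<eco_partition> masked 0 | subtropical 16876 | transition 5807 | temperate 17317
```

The generating truth put the three pairs' boundaries at rows 85, 100 and
115 (a 31-row band on 1-km cells); the fitted band's mean width of 29 km
recovers it to within 7 %. Each pair's index system retained the four
covariates with *q* > 0.3, e.g. for the conifer pair:

```r
print(fit$qtables[["II"]])
```

```
q-table for pair II
     variable        q p_value
           pa 0.724723   0.005
          dem 0.697753   0.005
        tadem 0.600461   0.005
    meantem01 0.514892   0.005
 silt_content 0.011649   0.005
 sand_content 0.001303   0.005
 soil_organic 0.001058   0.025
```

The drivers explain 51–72 % of covariate variance across the two vegetation
classes; the soil-like nuisance fields explain ~1 % or less (note that with
~6,000 labeled pixels even a negligible *q* can be formally significant —
selection is by effect size, not p-value). The three-zone characterization
(`fit$zone_table`) reports, per index, the three-strata *q* and the per-zone
means in raw covariate units, with the transition zone intermediate on every
monotone driver, e.g. annual-precipitation-like `pa`: 10.06 (subtropical),
5.61 (transition), 0.00 (temperate), *q* = 0.52.

`plot(fit)` draws the partition with the per-pair boundary polylines;
`run_all("run.yaml")` executes the same workflow from files on disk, writing
every intermediate artifact (q-tables, index systems, zone maps, boundary
GeoJSON, the transition polygon, width profile, zone table, graded quadrats)
plus a manifest, byte-reproducibly under a fixed seed. A thin CLI lives at
`inst/cli/ecotone.R`.

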