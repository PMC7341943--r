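# rhizomorph

Morphometrics and stochastic growth simulation of chytrid rhizoid systems.

Chytrid fungi are unicellular, early-diverging fungi that feed and anchor
through **rhizoids** — anucleate, thread-like filaments branching out from
the cell body (thallus), the single-cell analogue of a mycelium. Rhizoid
development is quantified the way neurite arbors and hyphal networks are:
cells are traced from confocal z-stacks into the **SWC** neuron-morphology
format, and the traced trees are measured. `rhizomorph` is the measurement
side of that workflow, for researchers studying filamentous growth in
chytrids (or any SWC-traced branching structure):

* **SWC I/O and a validated tree model** — `readSWC()`, `writeSWC()`,
  `projectXY()`, with structural validation (single root, no cycles or
  dangling parents).
* **Morphometric glossary** — `morphometry()` and friends: total rhizoid
  length, tip/bifurcation counts, the rhizoidal growth unit
  (RGU = total length / tips, or mean inter-branch-point distance),
  frustum surface area, maximum Euclidean reach, local bifurcation
  angles, convex-hull cover area.
* **Branch events** — `detectBranchEvents()` compares consecutive frames
  of a time series and classifies each new branch **apical** (at the tip,
  parallel to the axis) vs **lateral** (inserted distally, founding a new
  axis) by explicit thresholds.
* **Fractal organisation** — `boxCountDb()` estimates the box-counting
  dimension Db (−slope of log N(s) vs log s) of the rasterized
  projection; `localDbMap()` and `radialDbProfile()` resolve the
  centre-to-growing-edge Db gradient.
* **Growth trajectories** — `fitGrowthRate()` (per-cell OLS slopes,
  group mean ± s.d./s.e.m.) and `compartmentElongation()`
  (diameter-scaled tip elongation over fixed intervals).
* **Group statistics** — `compareGroups()` / `pairedRhizoidContrast()`
  with Welch t or Mann–Whitney and `ns`/`*`/`**`/`***` star annotation.
* **A stochastic growth simulator** — `simulateRhizoid()` shares a
  constant elongation budget V across tips and branches as a Poisson
  process (rate λ, lateral with probability p_lat, insertion angles
  ~ truncated Normal), emitting SWC time series with stable node ids and
  a ground-truth event log. Presets encode the carbon-replete condition
  (V = 110.8 µm/h, λ = 4.6 h⁻¹, angles 81.4° ± 6.3), the carbon-starved
  "searching" phenotype and a chitin-microbead "feeding" contact
  phenotype.

## Worked example

Simulate one carbon-replete cell for 10 h, measure its final
reconstruction, and fit group growth rates over five cells:

```r
library(rhizomorph)

sim <- simulateRhizoid(rhizoidPreset("replete", seed = 11))
sim$series
#> RhizoidTimeSeries 'sim_s11': 11 frames, t = 0..10 h, ids stable

fin <- frames(sim$series)[[11]]
round(morphometry(fin)[, c("total_length", "n_tips", "rgu_ratio",
                           "max_euclidean", "mean_bif_angle", "cover_area")], 2)
#>   total_length n_tips rgu_ratio max_euclidean mean_bif_angle cover_area
#> 1         1108     44     25.18         114.9          78.94    8201.31
```

Total length is exactly V·T = 1108 µm (the budget is conserved); 44 tips
after 10 h at λ = 4.6 h⁻¹ (1 + Poisson(46) expected); the mean measured
bifurcation angle (78.9°) tracks the configured 81.4° ± 6.3 distribution;
RGU ≈ 25 µm means one tip per 25 µm of filament.

```r
cells <- lapply(1:5, function(s)
  simulateRhizoid(rhizoidPreset("replete", seed = s))$series)
fitGrowthRate(cells, "n_tips")
#> GrowthRateEstimate [n_tips]: 4.78 +/- 0.3634 (s.e.m., n = 5 cells)

boxCountDb(rasterizeSegments(projectXY(fin), pixelSize = 0.5))
#> FractalResult: Db = 1.312 (R2 = 0.998, 5 box sizes)

ev <- detectBranchEvents(sim$series)
head(ev, 3)
#>   time parent_node_id distance_to_tip axis_angle branch_class
#> 1    1             44        39.76082   69.48645      lateral
#> 2    1             62        36.91966   69.28033      lateral
#> 3    2            232        14.44113   41.65383      lateral
```

The tip-production slope recovers the configured 4.6 tips/h within one
s.e.m.; the mature system's Db ≈ 1.3 sits in the planar biological-fractal
band (1 = line-like, 2 = plane-filling); detected events carry the
geometry behind each apical/lateral call.

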