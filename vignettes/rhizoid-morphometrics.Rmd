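---
title: "Quantifying chytrid rhizoid development: models, metrics and the growth simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chytrid rhizoid development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The biological problem

Chytrid fungi are unicellular, early-diverging fungi that feed through
rhizoids: anucleate, thread-like filaments that branch out from the cell
body (thallus) to attach to and digest substrate. Functionally the rhizoid
system plays the role that a mycelium plays for hyphal fungi, and the same
comparative morphometrics apply — total filament length, tip number, the
growth unit (length per tip), branching angles, spatial reach and
space-filling (fractal) organisation.

`rhizomorph` operates downstream of imaging: its unit of measurement is a
traced reconstruction of one cell in the SWC neuron-morphology format (one
node per line: id, type code, x, y, z, radius, parent). Confocal z-stacks
are traced in neuron-reconstruction software and the exported SWC files are
read with `readSWC()`. No image processing happens in this package.

```{r}
library(rhizomorph)
tree <- readSWC("cell07_t10.swc")
morphometry(tree)
```

## Conventions of the measurement model

* **Structure labels.** SWC type codes map 1 → thallus, 5 → apophysis,
  3 → rhizoid, anything else → unknown. SWC has no fungal vocabulary, so
  we reuse the soma code for the thallus. The thallus root anchors the
  tree but is not rhizoid material: edges whose child is a thallus node
  are excluded from length and surface area, and the root is never a tip
  or bifurcation. Apophysis and unknown compartments are measured as
  rhizoid — they are part of the feeding structure's path.
* **Units** are micrometres throughout, right-handed axes with z the
  optical axis. Voxel anisotropy is assumed already corrected during
  tracing.
* **Degenerate input.** A root-only tree (a germling before germ-tube
  emergence) is legal and yields zero-valued or missing rhizoid metrics
  rather than errors. Zero-length edges — duplicated points from dense
  tracing — are contracted before every computation.
* **Projection.** Cover area, rasterization and box counting work on the
  XY projection (`projectXY()`), mirroring analysis of
  maximum-intensity-projected stacks.

## The morphometric glossary

`morphometry()` assembles one record per tree:

| column | meaning |
|---|---|
| `total_length` | sum of non-thallus edge lengths (µm) |
| `n_tips`, `n_bifurcations` | non-root leaves; non-root nodes with ≥ 2 children |
| `rgu_ratio` | total length / tips (µm) — the growth-unit ratio |
| `rgu_segment` | mean inter-branch-point path length (µm) |
| `surface_area`, `surface_area_total` | frustum lateral areas; `_total` adds the thallus sphere |
| `max_euclidean` | straight-line reach from the root (µm) |
| `mean_bif_angle` | mean pairwise daughter angle at bifurcations (degrees) |
| `cover_area` | convex hull of the XY projection (µm²) |

Two RGU definitions coexist in the literature: the verbal definition — the
distance between two bifurcations — and the comparative growth-unit ratio,
total length over tip number. We provide both; the ratio form is the
default used in trajectory comparisons. Because the inter-critical-point
segments partition the edge set, the segment form is computed in closed
form as (total edge length) / (tips + bifurcations); the test suite checks
it against explicit segment enumeration.

Two numerical choices matter for angles:

* Daughter directions at a bifurcation are chords to the first node at
  path offset ≥ 0.5 µm (`minOffset`), not to the immediate child, which
  suppresses quantization noise in densely sampled traces.
* Cover area uses the convex hull rather than an alpha-shape: the hull is
  parameter-free and deterministic, at the cost of overestimating concave
  territories.

Reported surface areas are deliberately emitted in both variants because
published whole-cell area rates are inconsistent with any fixed rhizoid
diameter, suggesting they may describe the thallus only; keeping both
columns lets the user choose the comparison.

## Branch events and the apical/lateral dichotomy

Between consecutive frames of a `RhizoidTimeSeries`,
`detectBranchEvents()` reports one event per node that holds ≥ 2 children
in the later frame but fewer (or did not exist) in the earlier one. Each
event carries:

* `distance_to_tip` — path distance from the insertion point to the tip of
  its parent filament *in the earlier frame* (0 for a tip split);
* `axis_angle` — angle between the new branch's initial direction and the
  local filament axis, taken as the chord over the ~2 µm of path upstream
  of the insertion point.

Classification is a pure threshold rule (`classifyBranch()`): apical iff
`distance_to_tip <= dTip` AND `axis_angle <= thetaPar`, lateral otherwise.
The source imagery supports only verbal definitions ("at the tip, parallel
to the axis"), so the thresholds default to `dTip = 1` µm and
`thetaPar = 30`° and are exposed as arguments — they are the only free
parameters of the branching module and are meant to be swept. When a tip
split produces two new daughters, the daughter best aligned with the axis
is treated as the continuation of the filament and the other as the new
branch. When node ids are not stable across frames, nodes are greedily
matched by nearest neighbour within 1 µm and ambiguous matches abort
rather than guess.

## Fractal analysis

`rasterizeSegments()` draws the projected skeleton as 1-px-wide digital
lines (default pixel 0.5 µm ≈ confocal lateral sampling).
`boxCountDb()` counts occupied boxes over a geometric size series —
powers of 2 from 2 px to a quarter of the grid's short side, fitted over
all sizes with no manual range pruning, so no per-image tuning exists —
and reports Db = −slope of log N(s) on log s plus the fit R².
`localDbMap()` repeats the estimate in sliding windows (default 64 px
window, 16 px stride; windows under 10 foreground pixels are missing), and
`radialDbProfile()` averages the map in annuli about the thallus to
quantify the centre-to-growing-edge gradient. The estimator is validated
against its analytic limits: a straight line gives Db ≈ 1, a filled plane
Db ≈ 2, an isolated point Db ≈ 0.

## Growth trajectories and elongation

`fitGrowthRate()` fits an OLS slope of metric versus time per cell, then
aggregates mean ± s.d./s.e.m. across cells. Rates are per-cell slopes
rather than a pooled regression to mirror biological replication — the
between-cell variance is the error that matters at n = 5; endpoint
differences were rejected as noisier. `compartmentElongation()` measures,
for each terminal compartment present at the start of a sampling interval
(default 30 min), the path length it adds over the interval — path length
along the filament, not Euclidean displacement, because filaments curve —
and scales it by the compartment diameter (2 × mean radius of the added
path), reporting both the raw and the diameter-scaled rate.

## The growth simulator

`simulateRhizoid()` is a first-class synthetic-data generator whose
defaults *are* the observed study conditions, not a fitting device. Its
model:

* **Shared elongation budget.** The system elongates at a constant total
  rate V (µm/h) split across active tips each step. This reproduces the
  observed linear growth of total length while tips multiply; a constant
  per-tip rate would give super-linear length growth, contradicting the
  trajectories.
* **Constant per-system branch rate.** Events arrive as Poisson(λ·dt);
  each adds exactly one tip, so tip number is 1 + Poisson(λt) — linear in
  time, as observed. Lateral with probability `p_lat` (inserted at a
  length-uniform point on existing filament, at an angle drawn from
  Normal(µ, σ) truncated to (0°, 180°) about the local axis, random side);
  otherwise apical (a tip splits into daughters at ± angle/2 about its
  heading).
* **Tip persistence.** Headings random-walk with per-step s.d. κ
  (default 2°/step at dt = 0.01 h): filaments are locally straight but
  meander over hours. Growth is planar (z = 0) by default, as cells
  develop along the dish bottom; `zSigma > 0` enables a 3-D mode.
* **Determinism.** One seeded generator, fixed draw order (elongation
  noise per tip in order, then branch arrivals): identical seeds give
  byte-identical SWC series. Branch insertions place the daughter node at
  a 10⁻⁶ µm offset which is charged against the next step's budget, so
  total length equals V·T to within ~10⁻⁶ µm at all times.

The carbon-replete preset encodes the printed growth statistics:
V = 110.8 µm/h, λ = 4.6 events/h, angles 81.4° ± 6.3, p_lat = 0.85 (the
lateral-dominance figure prints significance, not a ratio, so the value is
config-exposed). Filament diameter defaults to 0.5 µm and the thallus
radius to 2.5 µm, typical of the imaged cells; dt = 0.01 h and hourly
frames mirror the hourly reconstruction series.

The starved preset encodes the carbon-starvation searching phenotype as
*directions* — the graphical source gives no magnitudes — by halving λ
(2.3 events/h), widening the insertion angle (µ = 95°) and maintaining V:
the same material is spread over fewer, longer, wider-spreading filaments,
which yields greater reach, higher RGU and larger cover area at matched
time. The bead preset adds a spherical chitin particle (radius 8 µm,
centre 30 µm from the cell) in otherwise carbon-free medium: filament
within 1 µm of the bead surface switches to a feeding regime (lateral rate
12 events/h, elongation weight 0.25) while non-contact filament keeps the
searching parameters — reproducing the contact/non-contact contrast via
`beadContactSplit()`.

What the generator does **not** emulate: tracing noise and gaps, tip
retraction or death, rhizoid fusion, thallus expansion, non-planar growth
by default, and any mechanistic cell-wall/actin control of branching.
Passing parameter-recovery tests therefore shows the measurement chain is
faithful on idealized traced geometry of the right statistical shape — not
that real confocal traces are free of segmentation artefacts.

## Group statistics

`compareGroups()` reports descriptives plus a two-sided Welch t test by
default — the source figures annotate stars without naming their test, and
unequal variances are the safe assumption for morphometrics — with
Mann–Whitney as a small-n alternative; both are labelled in the output.
Stars map strictly: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, else
`ns`. No multiple-testing correction is applied by default (stars are
per-metric, as presented); `adjust = "BH"` enables Benjamini–Hochberg.

## Validation design and problem sizes

The package validates itself at desk scale:

* every metric is checked against an independent brute-force traversal
  implementation on 100 random trees (≤ 300 nodes) at 10⁻⁹ relative
  tolerance, and against hand-computed values of a Y-shaped toy tree;
* parameter recovery runs 5 simulated cells (replete, 10 h, hourly
  frames) for rate slopes and pools ≥ 100 branch events across seeds for
  angles; phenotype-direction checks use 20 seeds per preset;
* fractal limits use 512² grids and a designed centre-dense fixture for
  the radial gradient;
* determinism and SWC round-trip identity are asserted byte-for-byte.

These sizes keep the full suite under a few minutes on one CPU while
leaving the stochastic checks enough power; they are stated here so users
can scale them up for their own confirmation runs.

## Known limitations

* The branching thresholds (`dTip`, `thetaPar`) are declared, not
  inferred: with the default 30° parallelism cut, a symmetric simulated
  tip split (daughters at ± 40° for an 81° angle draw) classifies as
  lateral. Classifier outputs should be interpreted relative to the
  thresholds used, which is why the ground-truth event log accompanies
  every simulation.
* Box-counting choices (pixel size, box range, window, stride) follow
  deterministic defaults rather than published supplementary parameters;
  absolute Db values should be compared only within a fixed
  configuration.
* Cover area is convex, so strongly concave territories are
  overestimated.
* Frame matching for unstable ids is greedy nearest-neighbour within
  1 µm: adequate for hourly frames of slow growth, not for fast or dense
  material.
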