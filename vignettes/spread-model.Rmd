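---
title: "An agent-based model of spotted-lanternfly spread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of spotted-lanternfly spread}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slfspread)
```

## The problem

The spotted lanternfly (*Lycorma delicatula*) is a univoltine invasive
planthopper spreading through the eastern United States. Its natural
dispersal — walking nymphs plus short adult flights over one annual life
cycle — covers only a few kilometres per year, yet new county-level
detections appear far beyond that range, consistent with egg masses and
gravid females hitchhiking on vehicles. `slfspread` simulates this spread
as an agent-based model on a gridded habitat-suitability landscape and asks
how much human-mediated "jump" dispersal is needed to reproduce an observed
county-level detection record.

## The annual update

One time step is one full life cycle (egg → nymph → adult → oviposition),
so the model state is simply the number of individuals per 4-km cell. Each
year applies, in order:

1. **Survival.** A single annual adult-survival rate
   $u \sim \mathrm{unif}(0.5, 0.9)$ is drawn and applied to every cell as
   binomial thinning, so the expected surviving total is $uN_{t-1}$ while
   per-cell counts stay integer.

2. **Growth.** The global target
   $N' = N + rN\,(1 - N/K) + V,\; V \sim \mathrm{unif}(-0.5, 0.5)$
   is rounded to the nearest integer (ties away from zero) and floored at
   zero. The increment is allocated across occupied cells multinomially in
   proportion to their current counts; a deficit is removed by the same
   proportional rule. The global recursion is therefore reproduced exactly
   (up to rounding), and the model is agnostic about within-cell
   demography, which the published growth equation does not resolve.
   $K$ defaults to $10^5$, large enough that growth is effectively
   exponential at simulated population sizes; any other value (e.g.
   $10^{15}$) can be configured.

3. **Movement.** Every individual must leave its natal cell for one of its
   up-to-8 Moore neighbors. Each individual draws a movement coefficient
   $q_i \sim \mathrm{Normal}(\bar q, 0.05)$ clipped to $[0, 1]$; with
   probability $q_i$ it takes the neighbor with the highest suitability
   ("best choice", $\bar q = 0.99$), otherwise a uniformly random neighbor
   ("random", $\bar q = 0.01$). Ties in the suitability ranking break in
   row-major order so the ranking is deterministic; exploration comes only
   from the random branch. Movement conserves the total exactly.

4. **Human-mediated jumps.** With
   $d = $ mean over occupied cells of (count / max count), the step fires
   when $\mathrm{unif}(0, d) > \mathrm{unif}(0, 1)$, i.e. with probability
   $d/2$, so firing becomes more likely as densities rise. When fired, the
   number of events is $\lfloor \mathrm{U}\{1, h\} \cdot d \rfloor$ where
   $h$ is the scenario's maximum events per year. Each event samples a pool
   of occupied origin cells (capped at 10,000), draws 1–10 candidate
   origins from it, offsets each by independent
   $\mathrm{round}(\mathrm{Normal}(0, 30))$ cells per axis (120 km per
   axis on 4-km cells, about 169 km along the diagonal; out-of-bounds
   offsets are re-drawn up to 100 times, then the candidate is skipped),
   keeps the most suitable candidate destination, and seeds it with
   $\mathrm{U}\{1, 60\}$ founders. Founders join the population after
   movement, so they first act in the following year — they emerge at the
   subsequent time step.

A replicate starts with 1000 individuals in a single origin cell and runs
13 years by default. The published design crosses
$r \in \{0.25, 0.5, 1.0, 1.5\}$, $\bar q \in \{0.01, 0.99\}$ and
$h \in \{0, 3, 5, 7, 10\}$ — 40 scenarios, and at 1000 replicates of 13
years, 520,000 annual simulation steps.

## From replicates to predictions and metrics

Per scenario and year, each replicate's cumulative ever-occupied cell set
is binarized, the replicate stack is averaged into a per-cell occupancy
probability, and cells with probability $\ge 0.95$ (inclusive, matching
"0.95 or greater") become the high-confidence prediction. Stacking is
per-year because evaluation is per-year; a current-occupancy
(non-cumulative) mode is available for sensitivity analysis.

Evaluation overlays predicted cells on a county map: a county is
*predicted* if it contains at least one predicted cell and *observed* if
its first detection is at or before the evaluation year. All four
confusion cells are counted at county level so that
$tp + fp + fn + tn$ equals the county count; a cell-level false-positive
count is available behind a flag for users who prefer the asymmetric
reading. Precision, Recall and $F1 = 2PR/(P+R)$ use the 0/0 → 0
convention, which only affects degenerate scenarios. `summarize_metrics()`
emits the mean ± SE table per design factor that downstream ANOVA or
post-hoc analyses consume; those analyses themselves are out of scope here.

## Synthetic data

`synth_suitability()` emulates the structure of a species-distribution
surface for this system: a near-zero background, a few narrow
high-suitability corridors (road/rail networks where tree-of-heaven, the
preferred host, thrives) and Gaussian "hub" bumps with radially decaying
suitability, so best-choice movement has stable local maxima to climb.
Default parameters were calibrated once against the published surface
summary — cell values with mean 0.032, SD 0.093 and maximum about 0.81 —
and the calibration is checked by a test at 50% relative tolerance.
What the generator does *not* emulate: the spatial autocorrelation of real
climate covariates, the fractal geometry of real road networks, and the
coastline/extent effects of a real map. Passing tests on these landscapes
therefore validate the pipeline's mechanics, not the realism of any
particular geographic forecast.

`synth_counties()` builds a Voronoi tessellation around random seed cells —
contiguous, exhaustive, deterministic given its seed. `synth_observed()`
runs one ground-truth replicate under a known configuration and reports
each county's first year of occupancy, filtered through an explicit
per-year detection probability (default 1, reproducing the implicit
assumption that arrival equals detection; lower values support robustness
checks).

## The desk-scale recovery study

`headline_study()` is the package's scaled-down analogue of the full
design: a 150 × 150 landscape, 60 counties, truth generated with
$h^\* = 3$, and the scenario set
$\{h = 0, 3, 5, 7, 10\} \times \{\bar q = 0.01, 0.99\}$ at 50 replicates of
10 years, with $r$ fixed at 1.0 (the middle of the published range) for
both truth and scenarios. These sizes are the package's default desk
profile; the full published profile (1000 replicates, 13 years) runs from
the same configuration schema. The ground truth uses random movement
($\bar q = 0.01$) so that its single replicate actually realizes jump
events and the synthetic record shows the qualitative pattern of the real
one: a growing core plus satellite counties beyond natural range.

### A structural limitation worth knowing about

The density signal $d$ is the mean of per-cell counts normalized by the
*maximum* per-cell count. Under best-choice movement nearly all
individuals funnel into the locally best cell, so most occupied cells hold
a tiny fraction of the maximum and $d$ stays near zero; the event count
$\lfloor \mathrm{U}\{1, h\} \cdot d \rfloor$ then rarely reaches 1 for
small $h$. In this implementation, faithful to the printed algorithm,
best-choice scenarios therefore produce almost no jump events, and
random-movement scenarios produce them mainly in the first years after
introduction while densities are still even. Jump destinations also vary
across replicates, so individual jump-colonized cells seldom reach the
0.95 occupancy threshold at 50 replicates. The desk-scale study
consequently shows only a weak recall advantage for human-movement
scenarios rather than a dramatic one — a property of this density
normalization interacting with movement concentration, documented here so
users interpret scenario contrasts accordingly.

## Numerical choices

- Grid coordinates are 0-based `(row, col)` with row 0 the top raster row,
  for unambiguous raster round-tripping; no-data raster cells become
  suitability 0 so they can never be ranked best.
- Boundaries are hard: edge cells have fewer neighbors, and jump offsets
  landing outside are re-drawn (up to 100 times) rather than clamped,
  which preserves the distance distribution.
- Counts that enumerate discrete things (events, pool sizes, candidate
  iterations, founders) use inclusive integer uniforms on
  $\{a, \dots, b\}$.
- The growth target rounds half away from zero (R's `round()` is
  half-to-even).
- Each replicate runs under one seed; replicate seeds derive from the
  scenario seed plus the replicate index, and scenario seeds from the
  experiment seed plus the scenario index, so any artifact can be
  regenerated in isolation and execution order is irrelevant.
- Degenerate inputs are absorbing or empty by design: an extinct
  population stays extinct (when $h = 0$), an empty state has density 0,
  and empty candidate lists simply skip an event.

## Known limitations

- Wind-assisted dispersal is deliberately absent, as in the source model.
- Within-year life stages are not resolved; the annual composite step is
  the finest temporal unit.
- GeoTIFF support reads band values through the `tiff` package but does
  not parse geo-referencing tags; ESRI ASCII grids carry their
  geo-transform and are the round-trip format.
- The density-normalization behavior described above limits how strongly
  human-mediated movement can express itself at small $h$.
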