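---
title: "Seasonal, guild-specific ecological networks: models and methods"
author: "guildnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal, guild-specific ecological networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guildnet)
```

## The problem

Coastal landscapes concentrate migratory stopover habitat, rapid
urbanisation and intense seasonal recreation in a narrow strip. Whether a
bird can move through such a landscape depends on which guild it belongs to
(wading birds, songbirds, raptors, swimming birds differ in mobility and
barrier sensitivity) and on the season (stopover, breeding and wintering
impose different habitat needs, and human recreation pressure itself is
seasonal). `guildnet` implements a complete analysis chain that makes both
axes explicit:

1. presence–background habitat suitability per species and season
   (maximum-entropy model),
2. guild-level ecological **source patches** from binarised suitability,
3. guild- and season-specific movement **resistance surfaces**, including a
   recreation-pressure factor estimated from GPS trajectories,
4. **circuit-theory connectivity**: cumulative current maps, least-cost
   corridors, pinch points and current-flow centrality,
5. graph **connectivity indices** (alpha, beta, gamma) of each network, and
6. a seasonal **conservation-priority map** overlaying kernel densities of
   the five network elements.

A seeded synthetic-landscape generator stands in for the (undeposited)
field data, so every stage is testable end to end.

## Habitat suitability model

For a species–season dataset with presences $x_1,\dots,x_m$ and background
points $b_1,\dots,b_n$, the model is the penalised maximum-entropy
(Gibbs) density over feature expansions $f(x)$:

$$\hat\beta = \arg\min_\beta\; \log \sum_i e^{\beta^\top f(b_i)}
  \;-\; \frac1m \sum_j \beta^\top f(x_j)
  \;+\; \sum_k \lambda_k |\beta_k|.$$

Feature classes follow the standard vocabulary — linear (L), quadratic (Q),
forward/reverse hinge (H, 10 interior knots by default), pairwise product
(P) — on covariates min–max standardised by the background; categorical
covariates (land use, soil) always enter as one indicator per class and
never join products. The per-feature penalty is
$\lambda_k = rm \cdot c_{\text{class}} \cdot \mathrm{sd}_b(f_k)/\sqrt m$
with class constants 1 (L/Q/P), 0.5 (hinge), 0.25 (categorical), all
scaled by the regularization multiplier $rm$. The objective is convex; we
solve it with damped diagonal proximal-Newton sweeps (all coordinates
soft-thresholded against the diagonal Hessian of the log-partition, then a
backtracking line search on the penalised loss), stopping when the largest
Karush–Kuhn–Tucker violation falls below $10^{-5}$ or after 500 sweeps.
Predictions use the cloglog transform
$1 - \exp(-e^{H}\,p_{\text{raw}})$ of the background-normalised raw
density, the modern default output; because the transform is monotone, the
MaxTSS binarisation downstream is unaffected by this choice.

Model complexity is tuned over feature sets {L, H, LQ, LQH, LQHP} and
$rm \in \{0.5, 1, \dots, 4\}$: each candidate's AICc is computed on the
full fit (likelihood of presences under the background-normalised raw
model, $k$ = nonzero coefficients, following the common ENMeval
convention), and among candidates with $\Delta\mathrm{AICc} < 2$ the one
with the lowest omission rate under spatial-block cross-validation wins
(ties: fewer parameters, then lower $rm$). Blocks are a 2×2 checkerboard
over the presence bounding box — the simplest spatial blocking that
separates tuning folds geographically. Datasets with at least 15 records
use five-fold cross-validation for the final map; 10–14 records use
leave-one-out with one replicate per record; the final suitability raster
is the fold mean. Collinearity is screened per season: Spearman
$|r| > 0.8$ pairs lose their lower-jackknife-importance member,
iteratively. Jackknife importance is the normalised drop in training gain
when a covariate is excluded.

## Sources, resistance, circuits

Binary maps (MaxTSS threshold: the candidate score maximising training
sensitivity + specificity, lowest value on ties) are unioned across the
species of a guild per season; connected components (8-neighbour by
default, because coastal habitat mosaics are diagonal-rich) above the
guild's minimum area — 0.5 km² for songbirds, 2 km² for the other three
guilds — become source patches.

Resistance combines seven factors: recreation pressure (seasonal Gaussian
kernel density of trajectory points, 250 m bandwidth, rescaled to [0,1] by
the seasonal maximum), distance to roads, building height, night lights,
NDVI, land use and distance to water. Continuous factors are cut into five
equal-interval classes and mapped through a guild-specific score table
(1–100); land use is scored per class and guild. The default calibration
encodes the guild contrasts that matter: songbirds pay less for built-up
land, raptors are most sensitive to roads and night lights, water is
near-costless for swimming birds, dense vegetation is cheap for everyone.
Factor weights average two schemes: the analytic hierarchy process
(principal eigenvector of an expert pairwise matrix; the shipped default
matrix is the perfectly consistent one reproducing weights
recreation 0.228, building height 0.223, land use 0.148, night lights
0.146, NDVI 0.133, water distance 0.085, road distance 0.037) and the
entropy weight method computed from the scored rasters. Both the matrix
and the calibration tables are configuration, not code.

The resistance raster becomes a resistor lattice: valid cells are nodes,
neighbour pairs are edges with conductance $2/(c_a + c_b)$, diagonals
scaled by $1/\sqrt2$ — the standard raster-circuit convention. Patches are
collapsed to zero-resistance super-nodes. Kirchhoff systems are solved by
sparse direct factorisation of the reduced Laplacian (Matrix package);
per-cell current density is half the summed absolute incident branch
currents. Corridors link each patch to its four nearest neighbours by
cost-weighted distance (Dijkstra on the lattice with edge weight = mean
cost × step length in metres); pinch points are the top natural-breaks
class (of five) of the all-to-one cumulative current within the corridor
zone (cells whose summed distance to a linked pair exceeds the pair's
least-cost distance by at most the 10,000 cost-weighted-distance cutoff),
polygonised and kept when larger than 5 ha. Network importance uses
current-flow centrality on the patch graph with corridor cost-weighted
distances as resistances, classified high/medium/low by natural breaks.

The connectivity indices of a network with $V$ nodes and $E$
(deduplicated) corridors are
$\alpha = (E - V + 1)/(2V - 5)$, $\beta = E/V$,
$\gamma = E/(3(V-2))$; $\alpha$ and $\gamma$ are undefined below $V = 3$
and reported as missing rather than clamped, and a disconnected flag marks
$E < V - 1$.

## Strategic and priority areas

Ecological nodes are geometric intersections of corridor polylines from
*different* guilds within a season (points closer than one cell merged);
overlap areas are contiguous regions where two or more guild source layers
coincide. The priority map overlays five standardised kernel-density
layers (bandwidth 500 m for all elements, configurable per element):
sources weighted by mean habitat suitability, corridors by mean cumulative
current along the line, pinch points by area, nodes unweighted (their
density is their own concentration measure), overlaps by guild richness.
Each density is cut into five natural-breaks classes recoded 0–4, summed
with equal weights (0–20), and the composite is cut into three
natural-breaks classes, the top class being high priority.

## Numerical choices

* **Natural breaks** is the exact Fisher dynamic program (implemented in
  C++), with ties broken toward the lowest boundary; rasters beyond 10,000
  cells are classified from a deterministic stride over the sorted values
  (rather than a random subsample, so classification never depends on RNG
  state), and all cells are then assigned by the resulting breaks. Layers
  with fewer distinct values than classes fall back to quantile breaks
  with a warning; constant layers yield a single class.
* **Kernel densities** use an isotropic Gaussian truncated at 4σ,
  renormalised by the on-grid kernel mass so edge cells are not
  systematically downweighted and total mass is conserved.
* **AUC** is the Mann–Whitney rank statistic with half-credit ties;
  identical score distributions give exactly 0.5.
* **Thinning** is greedy with a seeded random processing order (the
  retained count can vary by seed); coordinate duplicates are collapsed
  first.
* Degenerate inputs (all-nodata surfaces, disconnected source/ground
  pairs, unmapped land-use categories, undefined AICc) fail loudly with
  informative messages rather than propagating silently; pipeline stages
  isolate such failures per species-season and continue.

## The synthetic landscape generator

`generate_covariate_stack()` emulates a coastal district on a local metric
plane (origin 0,0; areas and distances exact by construction): a sea
margin with a noisy shoreline plus inland water from the low quantile of a
smoothed field, two wandering roads, built-up land near roads, and
spatially autocorrelated continuous covariates as Gaussian-smoothed white
noise (default range 5 cells). Distance layers are exact Euclidean
distance transforms; seasonal climate grids share a base field plus
season-specific amplitude and noise, so seasons correlate but never
coincide. `generate_occurrences()` plants a known species–environment
response: a linear predictor over named standardised covariates is
rank-standardised and passed through the inverse cloglog of an affine
transform (30u − 27), which concentrates the planted niche in roughly the
top decile of the landscape — applying the inverse cloglog to the raw
linear predictor instead saturates over half the grid and caps even the
true model's discrimination near AUC 0.72, which would make planted-signal
recovery untestable. Sampling bias multiplies detection by a smooth
road-accessibility field raised to `bias_strength` (0 = unbiased).
Trajectories are correlated random walks seeded on roads and coastline
with per-season counts proportional to the seasonal multipliers (default
summer 3 : spring/autumn 1.5 : winter 1, peak-tourism heavy).

What the generator does *not* emulate: tidal dynamics, observer/checklist
semantics of citizen-science records, temporal autocorrelation of effort,
and real land-cover geometry. Tests passing on synthetic data therefore
demonstrate algorithmic correctness and recoverability of planted signals,
not ecological validity on real data.

## Problem sizes used by the tests

The shipped test-suite and demo sizes are chosen to exercise every stage
at desk scale: recovery checks use 40×40 grids with 200 presences and
1,000 background points; the end-to-end demo uses a 40×40 grid at 150 m
cells (6 km × 6 km, so guild minimum patch areas remain meaningful),
8 species across the 4 guilds, 4 seasons, a reduced tuning grid
(L/LQ × rm 1, 2) and 800 background points. Full-scale analyses would use
the paper-scale defaults in `default_run_config()` (10,000 background
points, the 5 × 8 tuning grid, 30 m cells).

## Known limitations

* Weights in the default AHP matrix and the guild score tables are
  documented defaults, not elicited expert judgments; sensitivity analysis
  of these weights is out of scope.
* Corridor adjacency uses a k-nearest rule (k = 4) by cost-weighted
  distance; other adjacency constructions (full Delaunay, cutoff-based)
  would change E and hence the indices.
* The cost-weighted-distance cutoff (10,000) is in units of the composed
  resistance surface (score 1–100 × metres); on differently scaled
  surfaces it should be adjusted in the configuration.
* Pinch-point and priority-class counts depend on natural-breaks
  classification and are sensitive to the current-map distribution;
  degenerate (uniform) maps yield none by design.
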