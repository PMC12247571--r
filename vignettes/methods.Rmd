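---
title: "Robust all-to-all phase-coupling detection with dual-dipole beamformers and sensor subsampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust all-to-all phase-coupling detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Phase-difference-based functional connectivity between brain regions is
usually estimated at the source level, by applying spatial filters to MEG
sensor data and computing coherence between reconstructed dipole time
courses. Such estimates are notoriously fragile: every location's estimate is
a mixture of the true local signal, leakage from the other dipole of
interest, and leakage of third-party sources and sensor noise. Seed
misspecification and the absence of a proper baseline compound the problem.

`beamconn` implements, end to end, an analysis scheme that addresses these
failure modes with three ingredients:

1. **Two-dipole (dual) unit-gain beamformers.** For every dipole pair
   $(r_1, r_2)$ a filter $W^\top = (H^\top C^{-1} H)^{-1} H^\top C^{-1}$ with
   $H = [h_1\, h_2]$ enforces the identity-gain constraint $W^\top H = I_2$:
   each row passes its own dipole at unit gain while *nulling* the partner,
   removing the zero-lag mutual leakage term from the pairwise cross-spectrum.
2. **A null-coherence bias estimate.** Under spatially white noise, the
   residual cross-spectrum of a non-interacting pair is proportional to the
   Hermitian inner product of the two filter rows, $\sigma\, w_1^\dagger w_2$.
   Holding a seed dipole fixed, $\sigma$ is estimated as the slope of a
   through-the-origin regression of $|\hat s_1 \hat s_2^H|$ on
   $|w_1^\dagger w_2|$ over all targets; normalizing by the estimated powers
   yields a 6-D "null coherence" volume — the coherence expected from leakage
   alone — which is subtracted from (or, for stabilized averages, divided
   into) the observed coherence volume.
3. **Sensor-array subsampling.** The whole reconstruction is repeated over
   random channel subsets (reference plan: 100 iterations of 50–150 of 275
   channels). Spatial noise in the difference maps varies across subsets and
   averages out, while genuine interactions recur. The aggregate is the
   z-like map $z = (\overline{\mathrm{coh}} - \overline{\mathrm{null}}) /
   \mathrm{sd}(\mathrm{coh} - \mathrm{null})$, with the sample (n−1) standard
   deviation across iterations.

Detection proceeds by relative thresholding of the aggregated volume (the
top `pct`% of $N^2$ entries, each unordered pair emitted once), clustering
suprathreshold edges in 6-D (two edges are adjacent when both endpoint
distances simultaneously fall within the chosen 3-D neighborhood radius),
discarding clusters whose two assemblies share dipoles (auto-connections),
and scoring a hit when one connection's assemblies come within 2 cm summed
distance of the true pair. Free-response ROC curves summarize hit rate
against the mean number of false-positive connections across the threshold
ladder.

## The generative model

Sensor data are complex Fourier-coefficient matrices
$X = \sigma X_s / \|X_sX_s^H\|_F^{1/2} + (1-\sigma) X_n / \|X_nX_n^H\|_F^{1/2}$,
with $X_s = HS$ and $S$ drawn from a circular complex Gaussian with
covariance $D A D$, $D = \mathrm{diag}(a, a, 1-a, \dots, 1-a)$, and $A$ the
identity except for the coupling entries $\rho e^{\pm i\varphi}$ between the
interacting sources. The population coherence between interacting sources is
exactly $\rho$ for any $a, \varphi$, and their amplitude exceeds the
background sources by $a/(1-a)$ (2.333 at $a = 0.7$). The reference design
uses 20 active sources, 2 interacting, and 350 observations — the count a
multitaper estimate yields from 50 one-second epochs at ±4 Hz smoothing
(7 Slepian tapers each).

```{r}
library(beamconn)
setup <- setup_forward(seed = 1)          # 275 sensors, 12 mm grid, sphere
sim <- simulate_dataset(setup$lead, setup$candidates,
                        rho = 0.3, phi = (4 / 17) * pi, a = 0.7,
                        snr_sigma = 0.6, seed = 42)
plan <- subsample_plan(30, c(50, 150), seed = 42)
ci <- invert_csd(sensor_csd(sim$X))
oriented <- orient_leadfield(setup$lead, ci)
agg <- run_subsamples(sim$X, oriented, plan, distances = setup$distances)
edges <- threshold_edges(agg, 0.005)
clusters <- cluster_edges_6d(edges, setup$grid)
conns <- filter_clusters(clusters, edges, setup$grid)
score_detection(conns$connections, sim$true_positions, setup$grid)
```

## What the synthetic generator emulates — and what it does not

The forward module replaces an anatomical BEM head model with the closed-form
field of a current dipole in a homogeneous conducting sphere (center at the
origin, radius 0.08 m). The 275 sensors are point magnetometers on a
golden-angle spiral over a spherical cap; the default geometry — shell radius
0.10 m (2 cm standoff) and cap fraction 0.75 — matches the standoff and
coverage of a whole-head axial-gradiometer helmet. Both parameters matter:
moving the shell several centimeters further out broadens the leadfields
enough to visibly degrade pairwise resolution, so they are part of the
model's definition, not free dials. Gradiometer baselines are not modelled;
the simulator only needs a physically plausible mixing matrix.

Simulation sources are grid dipoles drawn from the top 40% of gain-vector
norms (emulating the exclusion of locations the array barely sees) and
receive random tangential-dominant orientations, standing in for cortical
normals. Reconstruction uses the power-maximizing fixed orientation computed
from the data CSD, so the simulation and reconstruction orientation models
deliberately differ. Real-data features *not* emulated: correlated
empty-room noise (white noise is the default; a covariance-colored option
exists), gradiometer geometry, anatomical cortical constraints, and off-grid
source positions — simulation sources coincide with grid nodes, which makes
localization slightly easier than in a full-scale study design with a
separate cortical source mesh. Passing tests therefore demonstrate internal correctness and
the method's comparative behavior, not absolute real-data performance.

## Numerical choices

* **CSD inversion** is unregularized: exact inverse when full rank, truncated
  Moore–Penrose pseudo-inverse (relative eigenvalue tolerance $10^{-10}$)
  otherwise. A ridge option exists but defaults to 0.
* **Fixed orientation** restricts the 3-column gain to its numerically
  nonzero column space first (relative eigenvalue tolerance $10^{-8}$ on the
  3×3 gain Gram). In a spherical conductor the radial direction is exactly
  silent; without this restriction the output-power maximizer latches onto
  the silent direction. Orientations are computed once per dataset from the
  full-array CSD and reused across subsamples (a per-subsample option
  exists; measured effects were mixed).
* **All-pairs computation** is vectorized through the Gram matrices
  $G = H^\top C^{-1} H$ and $G_2 = H^\top C^{-2} H$. With the exact or
  Moore–Penrose inverse of the sample CSD, the projected cross-power
  $H^\top C^{-1} (XX^H/n) C^{-1} H$ collapses to $G$ (a Penrose identity), so
  the pairwise source CSD is simply the inverse of the 2×2 Gram block:
  cross $= -g_{ij}/\det$, powers $g_{jj}/\det$, $g_{ii}/\det$. A compiled
  kernel assembles the coherence, null-shape, and validity maps in one pass;
  tests pin it to the naive per-pair filter loop at $10^{-10}$ relative.
* **Pair validity.** A pair is excluded when the *diagonally normalized* 2×2
  Gram condition number $(1+|c|)/(1-|c|)$, $c = g_{ij}/\sqrt{g_{ii}g_{jj}}$,
  exceeds $10^6$ — normalization makes this a pure collinearity test,
  insensitive to depth-related scale differences — or when the dipole
  distance is below one grid spacing.
* **Null-scale fit** excludes the seed and targets within one grid spacing,
  requires at least 10 usable targets, and fits through the origin (an
  intercept would absorb true coupling). An optional `trim` fraction drops
  the largest-|cross| targets per seed before fitting; it is off by default
  because upward outliers may be true interactions, but it matters on very
  small grids where a strong interaction contaminates the handful of
  regression points.
* **Divide-mode correction** floors the denominator at $10^{-6}$ times the
  median valid null value and flags floored entries.
* **Aggregation** uses the arithmetic mean and the sample standard
  deviation; standard deviations below $10^{-12}$ are floored and flagged.
  The z-like aggregate is the detection statistic for the subsampled
  pipeline; the non-subsampled pipelines threshold the subtract-corrected
  coherence volume, and the imaginary-coherency comparator thresholds
  $|\mathrm{Im}\,\mathrm{coherency}|$ directly.
* **Thresholding** retains `round(pct/100 * N^2)` unordered pairs (ties
  broken by the lower flat index), which reproduces the printed ladder
  counts (for a 4416-dipole grid: 195 edges at 0.001%, 98 at 0.0005%).
  Edge counts use round-half-up.
* **6-D adjacency** defaults to the 26-neighborhood per endpoint (radius
  $\sqrt3 \times$ spacing, simultaneously on both endpoints); 18- and
  6-neighborhoods are available. On coarse toy grids the 26-radius is
  several centimeters and merges unrelated structure, so toy-scale analyses
  use the 6-neighborhood.
* **Assembly orientation** within a cluster is anchored at the peak-value
  edge: its endpoints seed the two assembly centroids and a consistency pass
  orients the remaining edges. Anchoring on the peak avoids overlap
  artifacts that arise when centroids are seeded from the unoriented edge
  lists.

## Problem sizes

The reference design (8 mm grid, 4416 dipoles, 100 configurations per
parameter cell, 100 subsample iterations) is a cluster-scale computation.
The package's working profile — the one its tests and the acceptance script
use — is a 12 mm grid (~1237 dipoles inside the 8 cm sphere), 20 random
configurations, and 30 subsample iterations, with detection restricted to
the 0.05%–0.0005% part of the threshold ladder; the looser ladder rungs are
available but produce edge sets whose clustering cost grows quadratically
while only populating the high-false-positive end of the FROC curve. Unit
tests use ~30–130-dipole toys.

## Known limitations

* The null-coherence model assumes spatially white sensor noise; colored
  noise violates the single-scale assumption (a covariance-colored noise
  option allows studying this).
* The CSD-based generator imposes the interaction phase in expectation, not
  per observation; whether the original design imposed it per observation is
  not documented.
* Relative thresholding always produces suprathreshold edges, so false
  positives are a matter of threshold choice, not an avoidable artifact.
* The sphere model's silent radial direction means deep and near-center
  dipoles are poorly seen; candidate screening removes most of them, and
  per-pair validity masks the rest.
* Under the white-noise default the combination of pair nulling and null-
  coherence subtraction suppresses spurious near-pair structure at zero
  coupling almost completely: in the package's zero-coherence replication no
  detected connection falls near the designated strong pair, and the best
  near-pair entries rank orders of magnitude below the detection thresholds.
  Recordings with spatially structured noise should be expected to behave
  less favorably — white noise is exactly the regime in which the null model
  is unbiased — so false-alarm behavior measured here is a best case.
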