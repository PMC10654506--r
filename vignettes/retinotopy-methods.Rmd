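---
title: "Quantifying single-cell retinotopy: the tiling match statistic and its generative model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-cell retinotopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinotile)
```

## The scientific problem

A topographic projection preserves neighborhood relations: neighboring
retinal ganglion cells (RGCs) should terminate at neighboring positions in
the superior colliculus (SC). `retinotile` quantifies how precisely this
holds at *single-cell* resolution, given two kinds of paired observations
per recording:

* the anatomical position of each unit in tissue coordinates (the centroid
  of an RGC axonal patch, or an SC soma; micrometers), and
* the functional position of the same unit in visual space (its
  receptive-field center; degrees).

Because the two spaces have different units and an arbitrary relative
rotation/scale, the comparison cannot be a direct distance. The package
implements two complementary statistics and a generative model that turns
them into biological parameter estimates.

## The tiling-pattern match

Each pattern is Delaunay-triangulated in its own space
(`delaunay()`), and edges are compared *by cell id*, never by geometry:

$$\mathrm{match} = 100 \cdot
  \frac{|E_A \cap E_B|}{\tfrac{1}{2}\,(|E_A| + |E_B|)} \; [\%]$$

where $E_A, E_B$ are the edge sets of the two triangulations as unordered
id pairs. The Delaunay graph is invariant under similarity transforms, so
the statistic is automatically insensitive to the unknown map between the
two spaces; 100% means every spatial adjacency is preserved. The chance
level (`bootstrap_chance()`) is the 95th percentile of the match after
randomly permuting the id correspondence of one pattern (10,000
permutations by default); only the pairing is destroyed, the geometry of
both patterns — hence their edge sets — is untouched, which also makes the
null cheap. We resolve cocircular degeneracies (e.g. four points on a
square) by the fixed index-ordered insertion of the incremental
triangulation, so results are exactly reproducible.

A complementary, metric measure is the *affine-optimal deviation*
(`affine_fit()`): the six-parameter affine map minimizing
$\sum_i \lVert A x_i + b - y_i \rVert^2$ defines the retinotopically ideal
pattern, and the per-cell residuals $\Delta_i$ (summarized as median ± MAD,
with the raw, unscaled MAD) measure the deviation from perfect linear
retinotopy in the target units.

## The generative model

The forward model has four steps, each exposed as a tested function:

1. **RGC RF mosaic** (`make_hex_lattice()`): a hexagonal lattice with
   spacing $L_\mathrm{RF} = 7.2°$ and i.i.d. per-axis Gaussian jitter of SD
   $0.1\,L$, emulating the dense regular packing of retinal mosaics.
2. **Axonal projection** (`project_axons()`): the RF pattern is scaled
   isotropically into tissue coordinates ($L_\mathrm{axon} = 100\,\mu m$
   per $7.2°$) and each terminal is displaced by i.i.d.
   $N[0, \sigma^2]$ per axis. $\sigma$ is the *projection jitter*, the
   model's first free parameter; $\sigma = 0$ gives a 100% match by
   construction.
3. **SC soma mosaic**: an independent jittered lattice with
   $L_\mathrm{soma} = 56\,\mu m$, centered on the same origin.
4. **Convergence** (`draw_convergence()`, `compute_sc_rfs()`): each SC
   neuron receives $k \sim$ zero-truncated Poisson(mean parameter
   $\lambda$) inputs from its $k$ nearest axons; connection weights are
   proportional to the overlap area between the dendritic disk (radius
   200 μm) and the axonal disk (diameter 135 μm), renormalized to 1; the
   SC RF center is the weighted average of the input RF centers. $\lambda$
   is the second free parameter.

Inference is simulation-based inversion (`sweep_sigma()`,
`sweep_lambda()`, `invert_curve()`): sweep the parameter, record the
median match and its 2.5–97.5% band over repetitions, and read off where
the median curve crosses the observed match level. The 95% CI of the
estimate is the parameter interval whose simulated band contains the
observed value. Median curves are isotonic-regressed before inversion
(decreasing for $\sigma$, increasing for $\lambda$) to guarantee a unique
crossing despite finite-repetition noise; crossings use linear
interpolation between grid points, and flat segments resolve to their
midpoint. A band curve that never reaches the observed level is clamped to
the grid end it saturates at.

## Parameters that matter, and their defaults

| parameter | default | unit | why |
|---|---|---|---|
| `L_rf`, `L_axon`, `L_soma` | 7.2, 100, 56 | deg, μm, μm | measured neighbor spacings of the three mosaics |
| `jitter_frac` | 0.1 | — | retinal-mosaic regularity; applied per axis (the radial-vs-per-axis choice is not observable at this regularity, per-axis chosen) |
| `dend_radius`, `axon_field_diam` | 200, 135 | μm | anatomical dendritic/axonal field sizes; "135 μm" is a diameter, so the overlap uses radius 67.5 μm |
| `grid_rows × grid_cols` | 9 × 9 | — | order of an experimental field of view (~25–60 usable cells) |
| `margin_rows/cols` | 1 | — | convex-hull Delaunay edges are unstable; match statistics on simulated lattices use interior nodes only (n = 49) |
| sweep grids | σ: 0–50 × 1 μm; λ: 1–10 × 0.25 | | fine enough that linear interpolation error is negligible against the simulation band |

Two modeling choices deserve comment. Poisson draws of $k = 0$ are
replaced by a zero-truncated Poisson: a neuron with no retinal input has no
RF and no counterpart in functional data. And if every disk overlap is zero
(possible only in pathological configurations), weights fall back to
uniform rather than failing.

## Receptive-field estimation

`reverse_correlate()` computes the response-weighted average of the
mean-subtracted binary checkerboard (fields 3.7° × 2.9°, 4 Hz, screen
±36.5° azimuth / ±22° elevation) over a 0.5 s window in 16.7 ms bins, with
the 4 Hz stimulus held piecewise-constant on the finer time grid. The peak
latency is the lag of maximal spatial deviation energy, and
`fit_rf_gaussian()` fits a signed-amplitude elliptical Gaussian there
(Levenberg–Marquardt, initialized at the frame extremum); the RF size
convention is $sd_\mathrm{long} + sd_\mathrm{short}$ (the mean of the two
1-SD diameters). Cells are excluded when the fit fails, when an SD exceeds
the screen half-extent, or when the peak energy's z-score against a
100-shuffle circular-shift null is below 3 — the inclusion rule is our
stand-in, as functional inclusion criteria beyond on-screen centers are
a free choice. `screen_filter()` then drops cells whose center falls in
the outermost field ring or off screen and flags recordings with fewer
than 10 survivors.

The synthetic recording generator (`synth_recording()`) is an LNP cascade:
unit-norm Gaussian spatial kernel, Gaussian temporal bump at the nominal
latency, softplus nonlinearity, Poisson event counts per bin. Defaults
(gain 4, baseline −3) give a few events per second — the scale of
deconvolved calcium event rates. It emulates response linearity and
Poisson variability but *not* adaptation, correlated noise, eye movements,
or deconvolution artifacts, so passing recovery tests demonstrate
correctness of the estimator, not robustness to every property of real
recordings.

## Numerical choices

* Delaunay triangulation is computed in compiled code (Bowyer–Watson,
  deterministic index-ordered insertion; predicates evaluated in extended
  precision with a bounded super-triangle so regular lattices are handled
  exactly). Collinear inputs raise an error.
* Ellipse/patch overlap fractions are rasterized at 0.2° (area error well
  under 1% at RF scales); disk–disk overlap weights use the closed-form
  lens area.
* All randomness flows from one root seed through named substreams
  (`derive_seed()`), so any stage reruns reproducibly in isolation.
* Outlier-trimmed correlations drop pairs outside the central 95% of
  either variable. Note the trim is not innocuous: on bivariate normal
  data with $\rho = 0.19$ it biases the correlation to ≈0.147 — worth
  keeping in mind when comparing trimmed and untrimmed values.

## Problem sizes used by the packaged analyses

The `analysis/` drivers and the acceptance script run the sweeps at
500 repetitions per grid value on the 9 × 9 default lattice; at this size
the median match at a grid value moves by well under one percentage point
when repetitions are halved, so the inversion is stable at the reported
precision. The synthetic-recording analyses use 10-minute stimuli and
15–20 cells.

## Known limitations

* The model is static: no developmental or structural plasticity, no
  cell-type-specific connectivity, and only RF *center* positions are
  simulated (not RF sizes or shapes).
* The permutation chance level depends strongly on the number of cells
  (≈29% at 25 lattice nodes, ≈16% at 49), and regular lattices give
  slightly higher chance levels than irregular experimental mosaics of
  the same size.
* Sequential inference (λ conditioned on the σ estimate) ignores the σ
  uncertainty in the λ CI, matching the sequential design it emulates.
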