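---
title: "Dispersal-speed analysis on mycelial networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dispersal-speed analysis on mycelial networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyphalTracks)
```

## The problem

Motile bacteria can disperse through water-unsaturated habitats by swimming
in the thin liquid film that surrounds fungal or oomycete hyphae ("fungal
highways"). High-speed video microscopy and automated spot tracking produce
frame-wise trajectories of individual cells moving on such a network. Because
cells cannot be re-identified once they leave the focal plane, the natural
unit of analysis is not the cell but the *independent speed measurement*:
one displacement between two consecutive frames divided by the inter-frame
time. Pooled over all trajectories of a population, these measurements form
a strongly right-skewed, heavy-tailed distribution: most measurements are
slow (cells in or near microcolonies, cells moving through crowded film),
while a small fraction reaches up to ~100 µm/s along open hyphae.

`hyphalTracks` implements the full analysis chain for such data:

1. reading TrackMate-style spot tables (`readTracks`),
2. instantaneous speeds and quality filters (`instantaneousSpeeds`,
   `applyFilters`),
3. maximum-likelihood fitting and information-criterion ranking of candidate
   speed distributions (`fitMLE`, `rankModels`),
4. a slow/fast regime split at an intersection of fitted probability density
   curves (`pdfIntersections`, `splitAt`), with a sub-range refit as a
   robustness check (`subrangeRefit`),
5. nonparametric two-population comparisons (`ksTwoSample`,
   `kruskalWallisTest`),
6. a seeded synthetic trajectory simulator that emulates the statistical
   structure of such experiments (`generateNetwork`, `simulateAgents`,
   `observeTracks`, `paperLikeDataset`), so the whole pipeline can be
   validated offline.

## Speeds and exclusion rules

The instantaneous speed of a cell between consecutive frames \(i\) and
\(i+1\) is
\[
  v_i = \frac{\sqrt{(x_{i+1}-x_i)^2 + (y_{i+1}-y_i)^2}}{t_{i+1}-t_i}.
\]
Pairs that span a frame gap contribute no sample: the path in between is
unobserved. Tracking is planar; a z column in an export is ignored with a
warning.

Three exclusion rules clean the pooled measurements (`filterConfig`):

* **minimum duration** (default 0.25 s): trajectories shorter in time
  correspond to cells crossing the focal plane transiently, whose apparent
  in-plane speeds are unreliable;
* **minimum path length** (default 5 µm): shorter trajectories are mostly
  positional rearrangements of cells inside microcolonies, not dispersal;
* **speed cutoff** (default 100 µm/s): individual samples above the cutoff
  are treated as tracking artifacts (e.g. identity switches between a cell
  leaving and another entering the focal plane).

The rules are applied in that order — the two trajectory-level rules first,
then the sample-level cutoff — and all exclusions use strict inequalities,
so boundary values (exactly 0.25 s, 5 µm, 100 µm/s) are retained. The
percentage excluded by the cutoff is reported with the post-trajectory-filter
sample count as denominator. The order and the denominator convention are
fixed and logged because reasonable alternatives exist; both choices are
configurable in `applyFilters` only through the documented `FilterConfig`
fields, keeping runs auditable.

Path length is a whole-trajectory property and therefore *does* accumulate
across frame gaps, unlike speed.

## Candidate distributions and fitting

Retained speeds live on the interval \((0, v_{\max}]\). Every candidate
single family (lognormal, Cauchy, normal, gamma, Weibull, exponential) is
truncated to that interval and renormalised; a Cauchy, in particular, has
support on all of \(\mathbb{R}\) and can only describe nonnegative,
hard-cut speeds after truncation. The uniform density on the support is the
seventh candidate, with no free parameters (its bounds are fixed by the
filter, which preserves identifiability of the mixtures). Each non-uniform
family also enters as a two-component mixture with a uniform background,
\[
  f(x) = w\, f_{\text{trunc}}(x) + (1-w)\,\frac{1}{v_{\max}}, \qquad
  w \in [0, 1],
\]
which captures the empirical structure of these data: a peaked slow
component plus a broad, nearly flat fast background. The default pool is
thus 7 single families + 6 mixtures.

Fitting is direct bounded likelihood maximisation (BFGS on transformed
parameters: log for scales, logit for the weight), not EM — the truncated
Cauchy has no closed-form EM steps, and a single numerical maximiser
treats all families uniformly. Multi-start protects against local optima of
the mixture likelihood: a moment-based start, a "peak subset" start (the
component initialised on the lower 70% of the data), a start at the nested
single-family solution with \(w = 0.98\), and seeded random perturbations
(20 starts by default). The boundary weights \(w = 0\) and \(w = 1\) are
evaluated exactly after optimisation; if one of them wins, the fit is
flagged as a boundary case and the nested single-family fit is attached.
This construction guarantees the nesting inequality
\(\log L_{\text{mixture}} \ge \log L_{\text{single}}\) exactly.

Models are ranked by information criteria with \(k\) free parameters
(the mixture weight counts; fixed uniform bounds do not):
\[
  \mathrm{AIC} = 2k - 2\log L,\quad
  \mathrm{BIC} = k\ln n - 2\log L,\quad
  \mathrm{HQC} = 2k\ln\ln n - 2\log L .
\]
BIC is the default ranking criterion; AIC, HQC and raw log-likelihood are
available. At the sample sizes of interest (\(n \approx 6000\)–7000) the
criteria almost always agree on the top model. `rankModels` reports the top
ten fits by default.

In pipeline runs the fitting restart count is configurable; the bundled
analyses use 3–5 restarts, which with the deterministic informed starts
(moments, peak subset, nested single) reproduces the 20-start optima on
these unimodal-plus-background data while keeping a full 13-model ranking
of ~6500 samples to a few seconds.

## Regime split at a density intersection

The slow/fast boundary is defined as a speed where the two populations'
fitted probability density curves intersect. `pdfIntersections` scans the
density difference on a 10,000-point grid and refines every sign change by
bisection to an absolute tolerance below 1e-6 µm/s; tangential contacts are
not crossings and are not reported. The pipeline searches inside a bracket
of (1, 10) µm/s — the zoomed-in low-speed view where the slow bulk of both
distributions lives — and uses the smallest root, logging all of them. Ties
at the threshold go to the fast regime (`v >= threshold`); for continuous
data the choice has probability zero of mattering, but it is fixed and
documented.

As a robustness check on the mixed character of the distributions,
`subrangeRefit` splits the data at 60 µm/s, refits each subset over its own
truncated support ((0, 60] and [60, \(v_{\max}\)]) — likelihoods would be
improper otherwise — and reports whether the top three fits on each side
are still mixtures.

## Nonparametric comparisons

`ksTwoSample` computes the two-sided two-sample Kolmogorov–Smirnov statistic
exactly as the supremum of the ECDF difference over pooled points. The
default p-value uses the asymptotic Kolmogorov distribution at effective
size \(n_e = n_x n_y/(n_x+n_y)\) with the standard finite-sample scaling
\(\lambda = (\sqrt{n_e} + 0.12 + 0.11/\sqrt{n_e})\,D\); an exact
full-enumeration p-value is used automatically for \(n_x + n_y \le 16\).
`kruskalWallisTest` uses midranks with the usual tie-correction factor
\(1 - \sum(t^3 - t)/(N^3 - N)\) and a \(\chi^2\) p-value; a seeded
permutation mode exists for small-sample verification. At the pipeline's
sample sizes the asymptotic p-values are indistinguishable from exact ones;
the exact/permutation modes exist so the implementations can be verified
against enumeration oracles at desk scale. p-values are reported for
completeness but the pipeline's conclusions are based on the distribution
fits and regime summaries, not on significance thresholds.

## The synthetic data generator

The simulator emulates the statistical structure the analysis assumes,
not the physics of flagellar propulsion:

* **Geometry** — a seeded branching random walk grows a trunk from an
  origin ("inoculated drop") toward a target with angular noise; side
  branches attach at trunk vertices. Agents move in 1D along origin-to-leaf
  polylines (arc length), reflecting at the ends, because cells follow the
  liquid film along hyphae rather than diffusing freely in 2D.
* **Behavioural states** — each agent is in one of three states:
  *microcolony* (isotropic jitter around an anchor, sd 0.006 µm),
  *slow* (per-step speeds from a lognormal law) and *fast* (per-step speeds
  from a heavy-tailed law truncated at a true maximum of 115 µm/s, so that
  the 100 µm/s filter excludes a small realistic percentage). Switching is
  Markovian: at a total rate (default 1/s in the strain presets) the state
  is redrawn from the configured proportions, which are therefore also the
  stationary occupancy.
* **Observation model** — positions are sampled every 0.024 s with
  isotropic Gaussian localisation noise (preset sd 0.008 µm), and a
  visible agent drops out of the focal plane with probability 0.006 per
  frame, returning after a geometric off-time (mean 0.5 s). Reappearances
  get fresh track ids by default, mirroring the impossibility of
  re-identifying unlabelled cells; this is exactly why measurements, not
  cells, are the unit of analysis.

`paperLikeDataset` packages two strain presets. Both share the microcolony
fraction (0.12), the observation model and a lognormal slow state; they
differ in state weights and in the fast-state law: Cauchy-tailed
(location 6, scale 14 µm/s) for the UWC1-like profile, lognormal-tailed
(meanlog 3.0, sdlog 0.9) for the KT2440-like profile. The preset values
are design targets calibrated once against the structure the analysis
expects — roughly two thirds of filtered measurements below ~5 µm/s, a
heavy tail reaching ~100 µm/s, slow-regime means near 2 µm/s and
fast-regime means in the low twenties, and a cross-population density
intersection inside the (1, 10) µm/s bracket — and then frozen. They are
*presets of this package*, not measured properties of any bacterial strain:
no generative parameters (state dwell times, per-state speed laws) are
published for the real system, so none of these values should be read as
biological claims.

What the simulator deliberately does not model: hydrodynamics and flagellar
physics, hyphal growth during imaging, cell division, cell–cell collisions,
and out-of-plane (3D) motion beyond the dropout process. Consequently,
passing end-to-end tests shows that the *pipeline* recovers the structure
it is designed to detect from data with realistic nuisance processes
(noise, fragmentation, jitter, truncation); it does not validate the
biological interpretation of any real dataset.

The generator assembles whole observed tracks, in deterministic order,
until the filtered dataset holds the requested number of measurements,
trimming only the final track. Identical seeds give bit-identical
track sets.

## Numerical choices and degenerate inputs

* Densities are renormalised with the component's truncated mass; a
  component whose mass inside the support underflows (< 1e-12) scores
  \(-\infty\) rather than producing NaNs.
* `fitMLE` needs at least 10 samples and all samples inside the support;
  zero speeds (possible only for noise-free synthetic data) are dropped by
  the pipeline before fitting, with a count kept in the report.
* Sub-range supports treat their positive lower bound as closed so that
  threshold-valued samples remain inside.
* Failed or non-converged fits are flagged, never silently dropped; a
  ranking in which every candidate failed is an error listing per-family
  reasons.
* All randomness (restarts, simulations, permutation tests) flows through
  explicit integer seeds; reports are byte-identical across reruns with the
  same config.

## Problem sizes used in the bundled checks

The test suite and the acceptance script run entirely on synthetic data:
parameter-recovery fits at n = 5000, model-selection recovery over 50
replicates at n = 3000, type-I calibration of the rank tests over 1000
null replicates at n = 50 per group, and two-population end-to-end runs at
the study's combined sample sizes (7124 and 6344 measurements). These sizes
were chosen to match the scale of the experiments the pipeline addresses
while keeping a complete run to desk scale.

## Known limitations

* The regime threshold is a *descriptive* device — an intersection of
  fitted curves inside an explicit bracket — not an inferred changepoint
  with uncertainty. Different candidate pools or brackets can move it; the
  report logs every root found.
* With two similar populations the density curves can be nearly parallel
  over part of the bracket, making the intersection location sensitive to
  sampling noise even when both slow fractions are stable.
* The mixture's uniform background is a pragmatic description of the fast
  tail, not a mechanistic model of fast transport.
* Information-criterion ranking compares only the models in the pool;
  "best fit" never means "true model".
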