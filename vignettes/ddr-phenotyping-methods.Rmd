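---
title: "Methods: quantifying DNA damage response phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying DNA damage response phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddrphenokit)
```

This vignette records the models, numerical choices and design decisions
behind `ddrphenokit`, in the spirit of a methods section: what each stage
assumes, which knobs matter, and what the synthetic-data validation does
and does not demonstrate.

## Image conventions

All images are numeric matrices normalized to `[0, 1]` regardless of the
source bit depth ("full scale" always means the dtype maximum: 255 for
8-bit, 65535 for 16-bit). Pixels are addressed `(row, col)` from the
top-left; every tabular interface uses 0-based coordinates so that files
round-trip unchanged through external tools.

## Segmentation

**Thresholding.** Foreground is `intensity > fraction_of_max`, with
`fraction_of_max = 0.0196` by default — 1.96% of the *maximum possible*
intensity, i.e. 0.0196 on the normalized scale or 5.0 on an 8-bit image.
We read "maximum possible" as full scale rather than the per-image maximum,
and use a strict inequality; both choices are explicit because either
interpretation changes the mask on dim images. Connectivity is 8-connected
by default (4 available), and a `min_region_px` debris filter removes
specks below a size floor.

**Nucleus detection.** Cell counting and seed generation use multiscale
Laplacian-of-Gaussian blob detection: the scale-normalized response
`-sigma^2 * Laplacian(Gaussian_sigma * I)` is computed on a geometric ladder of
scales (default 3–8 px, 6 scales), strict 3×3 spatial maxima that also
dominate adjacent scales become candidates, and overlapping candidates are
suppressed strongest-first (blob radius `sqrt(2) * sigma`). The response
threshold (default 0.1) was calibrated on the synthetic generator: planted
nuclei of 8–12 px radius respond at ≈ 0.35, while pixel noise at SNR 10
stays below ≈ 0.1. These defaults are configuration, not constants of the
method.

**Seeded flood fill.** Regions overlapped by ≥ 2 nucleus seeds are
under-segmented and are split by simultaneous multi-source region growing:
every foreground pixel is assigned to the seed with the smallest geodesic
(within-mask) distance. Distance is the 8-neighbour hop count with unit
diagonal cost — a deliberate, documented metric choice that makes the
partition reproducible and lets an independent brute-force implementation
verify it exactly; ties go to the lowest nucleus id, seeds are ordered
`(row, col)` before ids are assigned, and seeds landing on background are
snapped to the nearest foreground pixel within 3 px. The test suite checks
bit-exact agreement with an independently written relaxation-based
labelling on dozens of random blob masks.

## Shape metrics and morphology classes

**Eccentricity** comes from the second-order central moments of the pixel
set: with covariance eigenvalues `lambda1 >= lambda2`, eccentricity is
`sqrt(1 - lambda2/lambda1)` (0 for a circle, → 1 for a line).

**Roundness** is the isoperimetric ratio `R = 4*pi*A / P^2`, which is 1 for a
circle. A ratio of area to perimeter alone would carry units of length and
could not serve as a normalized shape descriptor, so the squared-perimeter
form is used and stated prominently in the docs.

**Perimeter estimation.** Counting boundary pixels biases `P` by up to
~30% depending on orientation, which would corrupt roundness. We
prototyped Crofton-style intercept counting with 2 and 4 directions, but
at 4 directions the estimator still misses an axis-aligned square's
perimeter by ~5% (and hence its roundness by ~10%), which is outside the
package's own accuracy targets. The shipped estimator instead traces the
marching-squares contour at the 0.5 level and smooths the vertex chain
with a circular Gaussian window (`sigma` = 1 vertex ≈ 1 px) before summing
chord lengths. This is asymptotically unbiased for smooth shapes; measured
errors are ≈ 1% for discs of radius ≥ 15 px, ≈ +3.5% roundness for sharp
squares (corner rounding), and ≤ 3% variation under arbitrary rotation.
Holes are ignored (the outer contour is measured); disconnected regions
are rejected and must be split upstream.

**DBSCAN morphology.** Cells are clustered in the
`(roundness, eccentricity)` plane with `eps = 0.15`, `min_samples = 45`
(the point itself counts, matching the common library convention). Both
features already live in `[0, 1]`, so the radius is used unscaled — an
explicit decision; standardizing the features would silently change the
meaning of `eps`. Clusters map to semantic labels by mean roundness
(highest → "round", lowest → "fibroblast-like"); mapping by cluster *size*
would fail whenever one phenotype dominates a condition. A lone cluster is
labelled by its own mean roundness against a 0.5 midpoint; more than two
clusters are all returned with a warning flag rather than forced into two
classes. Population summaries exclude noise points from the round-fraction
denominator.

## Foci quantification

The original acquisition software's internals are not public; the
detection operator here is this package's own definition and is validated
only against synthetic ground truth — it is never claimed to replicate the
original software's outputs. Detection is LoG blob detection (default
scales 1–3 px) restricted to each nucleus pixel set, followed by a
relative-contrast gate: a blob survives if its peak exceeds the nucleus
median intensity by at least `rel_threshold` (default 0.5) of the
nucleus's median-to-max range. Counts are raw foci per nucleus (not
integrated intensity), matching the foci-per-nucleus readout used in
practice. Nuclei smaller than the largest LoG kernel's central lobe are
skipped with a recorded reason.

**Mitotic exclusion.** Mitotic (condensed, bright) nuclei must not enter
foci statistics. No published rule exists for the original pipeline, so
the filter is a declared surrogate: exclude a nucleus when its mean DAPI
intensity exceeds `intensity_factor` (default 2.0) times the population
median *and* its area is below `area_factor` (default 0.5) times the
median area. The synthetic generator renders mitoses at 0.55× radius
(≈ 0.3× area) and ≥ 2× interphase mean intensity, so the default filter
separates them with margin; both factors are configurable for real data,
where the mitotic phenotype is less stereotyped.

## Dose–response and growth models

Two families are fitted by nonlinear least squares (Levenberg–Marquardt):

- `LL4(x) = c + (d - c) / (1 + exp(b (ln x - ln e)))`, ED50 `= e`;
- `EXD3(x) = c + (d - c) exp(-x / e)`; the package defines its ED50 as
  `e ln 2`, the dose at which the decay term halves, since no standard
  definition exists for this family.

Initialization is deterministic: `c0 = min(y)`, `d0 = max(y)`,
`e0 = geometric mean of doses`, `b0 = 1`; `e` is constrained positive.
Replicates enter as individual observations (no pre-averaging) so the
residual degrees of freedom are honest; CIs are asymptotic Wald intervals
with t-quantiles on `n - k` df (profile-likelihood intervals are out of
scope). Model choice uses the Gaussian least-squares AIC
`n ln(RSS/n) + 2(k + 1)` — the error variance counts as a parameter — and
ties go to LL4. An exact (noiseless) fit gives `AIC = -Inf`, which orders
correctly against any imperfect fit.

Doubling time is `1/slope` from OLS of `log2(signal)` on time; a
non-positive slope yields an undefined doubling time with a flag rather
than a nonsense number.

## Assay quantifications and statistics

- **Wound closure**: the wound is the largest *background* connected
  component of the coverage mask (robust to holes in the monolayer); the
  rate is closed area per hour. The upstream ImageJ macro is not
  re-implemented — only the downstream area computation.
- **Gel fragmentation**: no quantification method is published for the
  original gels, so the package defines one: lightly smooth the lane
  profile, subtract the rolling-minimum lower envelope, and report the
  fraction of remaining signal below the well span, clipped to `[0, 1]`.
  The noise floor biases the fraction upward by a few percent at extreme
  fractions (the envelope sits ~1 noise-sd below the baseline); the
  round-trip error is ≤ 0.02 at the calibration point used in testing.
- **Statistics**: the Kolmogorov–Smirnov test against a normal with the
  sample's own mean and sd is provided because it is the conventional
  pre-check in this workflow; the estimated-parameter (Lilliefors) caveat
  makes it conservative and is documented rather than corrected. Pairwise
  comparisons use Tukey HSD on a one-way ANOVA or all-pairs Welch t-tests
  with exact Bonferroni adjustment `min(1, m p)`; which method applies to
  which figure is a user choice, so both are config options.

## The synthetic-data generators

The generators define the study conditions under which the pipeline is
validated:

- Nuclei scenes: 2048×2048 fields with ~300 nuclei (the 250–500 per image
  regime of confocal foci screens), radius 8–12 px, rendered as
  Gaussian-profile discs (`sigma = radius/2`, truncated at 2.5 sigma) — not hard
  discs, so LoG responses behave as on real chromatin. Background 0.05,
  peak 0.7, noise sd 0.02 by default; no intensity statistics were
  published for the reference instrument, so these are calibration
  choices, stated once and not tuned per test.
- Cell scenes: filled ellipses in two families — round (eccentricity
  0.05–0.25) and fibroblast-like (0.85–0.95), areas 1200–2000 px² — on a
  jittered grid; a stated fraction of cells is placed in touching pairs so
  under-segmentation splitting is exercised. The family gap is generous by
  construction; passing the 95% classification target therefore shows the
  chain works, not that real morphologies are this separable.
- Foci scenes: per non-mitotic nucleus, a fixed or sampled number of
  Gaussian spots (`sigma` 1.5 px, peak 0.6) with a minimum pairwise
  separation; infeasible packings raise a placement error rather than
  silently dropping foci.
- Tables: LL4/EXD3 viability with additive Gaussian noise; exponential
  growth counts with multiplicative noise; bimodal gel lanes whose
  inside:below signal split equals the requested fraction exactly before
  noise; wound mask pairs with exact pixel accounting.

Every generator is a pure function of its spec plus a seed (verified
bit-identical on rerun) and re-measuring noiseless scenes with ideal
operators recovers the ground truth exactly.

**What the validation does not show.** Real microscopy adds illumination
gradients, out-of-focus light, chromatic shifts, clumped colonies and
heterogeneous chromatin texture, none of which are simulated. The
validation demonstrates internal correctness (the algorithms compute what
they claim on data matching their assumptions), not field performance on
arbitrary instruments.

## Problem sizes used in the test suite

The suites run dense-scene detection on a 1024² field with 300 nuclei,
morphology on two 2048² fields with 200 cells each, foci recovery on an
1800² field with 200 nuclei, 100 seeded replicates per family for model
selection, and 1000 seeded null replicates for the Tukey family-wise error
calibration — sizes chosen to estimate each rate with useful precision
while keeping a full run on a single CPU in a few minutes.

## Known limitations

- The perimeter estimator rounds sharp corners (~3.5% roundness
  overestimate for squares); shapes with many concavities at the 1–2 px
  scale will read as slightly rounder than they are.
- DBSCAN border points are assigned in deterministic scan order; in
  well-separated data this is irrelevant, but overlapping clusters can
  shift a handful of border labels under reordering.
- The mitotic filter is a two-threshold surrogate; real mitotic figures
  (prophase vs metaphase) vary more than the rendered phenotype.
- EXD3 and LL4 are close relatives on narrow dose ranges; AIC separation
  of the families needs doses spanning well past the decay scale, as the
  model-selection suite's design does.
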