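---
title: "Measuring repeatability and reliability of cone mosaic annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring repeatability and reliability of cone mosaic annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coneagree)
```

## The problem

Adaptive-optics ophthalmoscopy shows the cone photoreceptor mosaic cell by
cell, and cone density — counted from manually clicked cone centres — is a
key endpoint when following retinal degenerations or gene-therapy trials
over time. A measured density change is only meaningful if it exceeds the
disagreement between two gradings of the *same* image. `coneagree`
quantifies that disagreement at two levels: individual cone identifications
(does a second grading mark the same cells?) and the derived bound cone
density (do different gradings give the same number?). Everything operates
on coordinate lists; image acquisition, registration and the clicking
itself are upstream of this package.

## Coordinates, units and scaling

All analysis happens in micrometres, with the origin at the ROI's top-left
corner, x rightward and y downward (raster convention). Pixel coordinates
are converted by the ROI's µm/px scale. Because retinal magnification
varies between eyes, that scale is adjusted in proportion to axial length
(`scale_factor()`): an eye 5% longer than the 24 mm reference gets a 5%
larger µm/px scale. The linear proportionality is a deliberate first-order
convention — more elaborate schematic-eye corrections exist, but they
require biometry this package does not consume, and both the reference
length and base scale are explicit parameters, never hard-coded.

Two loading rules are worth knowing. Points outside the ROI rectangle are
rejected (with a count), since they cannot take part in a bounded Voronoi
analysis. Bit-identical duplicate rows are collapsed to one point, also
with a count: they are double-click artefacts, and coincident points would
otherwise produce zero nearest-neighbour distances and degenerate Voronoi
cells.

## The adaptive matching threshold

Whether two selections mark the same cone is decided per ROI, not with a
fixed pixel radius: cone spacing varies several-fold across eccentricities,
and annotator jitter scales with it. All selections being compared are
pooled into one master list; each point's distance to its nearest *other*
point (same-annotator neighbours included) is computed, and the threshold
is the mean of those distances plus twice their SD. Where annotators
broadly agree, most nearest neighbours are the tight truth–regrade doublets,
so the mean tracks the localisation jitter while the SD absorbs the
heavier tail from missed and spurious marks.

Numerical choices: the SD uses the sample (n − 1) denominator, matching
what standard statistical software computes by default, and distances
exactly equal to the threshold count as within (the inclusive reading is
degenerate-case friendly: a threshold of 0 still matches coincident
points). A master list needs at least two points; fewer is an error.

One consequence deserves emphasis because it shapes the closed-loop tests:
the threshold adapts to the *observed* disagreement. If an annotator's only
error mode is localisation jitter (no misses, no spurious marks), the
nearest-neighbour distribution collapses onto the jitter scale, the
threshold lands around 2.5 jitter SDs, and roughly the upper 4% of the
jitter tail is declared unmatched. With realistic mixed noise the tail of
missed/spurious distances widens the threshold and this self-clipping all
but disappears. Pure-jitter regimes are therefore excluded from the
parameter-recovery tests on purpose, and recovery is checked in mixed
regimes.

## One-to-one matching and clustering

Candidate pairs are all cross-set pairs within the threshold. They are
accepted greedily in ascending distance order, skipping any pair with an
already-matched endpoint; exact ties break on (lower ground-truth index,
lower comparison index). This single global pass reduces to the intuitive
"the closer of two candidates wins" rule in unambiguous cases, resolves
the ambiguous ones deterministically, and makes the match count symmetric
in the two input sets — which in turn makes Dice independent of which set
is called ground truth, a property the test suite verifies on random
inputs. Greedy matching is maximal but not guaranteed maximum-cardinality;
on mosaics (points separated by roughly a lattice spacing, noise well below
it) it agrees with exhaustive maximum matching essentially always, and an
acceptance test bounds the discrepancy rate at 1% on 500 seeded problems.

With three or more graders the same idea runs over all cross-annotator
pairs of the pooled list: clusters grow by greedy agglomeration in
ascending distance, and a merge is rejected if it would put two selections
of one grader into the same cluster. Every selection ends in exactly one
cluster (singletons allowed). For two annotators this provably reproduces
pairwise matching, which the tests check; for more annotators it is a
deterministic, order-independent choice among the clusterings compatible
with the one-per-grader constraint. Confusion counts for an ordered
(ground truth, comparison) pair then read directly off the clusters, and
`rotate_ground_truth()` tabulates all k(k − 1) ordered pairs.

By construction `N_comparison = N_TP + N_FP` and
`N_ground_truth = N_TP + N_FN` hold exactly for every comparison — the
test suite asserts both identities on a thousand random problems.

## Bound cone density

Density from a finite window is biased by cells that spill over the
border. Bound density avoids this: Voronoi-tessellate the selections, keep
only cones whose cells are closed polygons entirely inside the ROI
rectangle (vertices on the boundary count as inside — the inclusive
convention keeps lattice examples exact and is configurable in principle;
cells are never clipped), and divide the cone count by the summed cell
area. Cells are built by intersecting perpendicular-bisector half-planes,
visiting neighbours in ascending distance with a security-radius stop:
once half the distance to the next neighbour exceeds the farthest current
cell vertex, no later neighbour can cut the cell. This is exact (up to
floating point) and fast enough for hundreds of ROIs. Analytic anchors pin
the implementation down: a square lattice with spacing s must give exactly
1/s², a hexagonal lattice 2/(√3 s²), and an independent tessellation
library reproduces areas and bound flags on random configurations to
1 part in 10⁶.

At least 4 non-collinear points are required (fewer cannot produce a bound
cell); "no bound cells" is a distinct error from "degenerate geometry", so
callers can tell an unusable ROI from an unusable point set.

## Density agreement statistics

**Bland–Altman.** Differences of paired per-ROI densities are tested for
normality (Shapiro–Wilk at α = 0.05 by default); on rejection both series
are log10-transformed — density distributions are right-skewed, and a
multiplicative grader effect is additive on the log scale. Bias is the mean
difference and the limits of agreement are bias ± 1.96 SD on the analysis
scale. Identical series short-circuit the (undefined) normality test and
report zero-width limits. Shapiro–Wilk is defined for n ≤ 5000; longer
series are tested on a deterministic evenly spaced subsample of 5000.

**ICC.** Agreement of densities across annotators uses ICC(2,1): two-way
random effects, absolute agreement, single measures — the standard form
when every target (ROI) is rated by every rater and raters are a sample of
possible graders. The estimate comes from the two-way ANOVA mean squares,
the 95% CI from the McGraw–Wong F-based formulas, and the qualitative band
follows Cicchetti (< 0.40 poor, 0.40–0.59 fair, 0.60–0.74 good, ≥ 0.75
excellent). The implementation was verified against an independent
closed-form oracle at 1e-9 and against a reference implementation from
another ecosystem on frozen values.

**Repeated-measures ANOVA.** Per-ROI values under each annotator form a
complete subjects × conditions matrix; the omnibus F is MS(conditions) /
MS(residual) from the within-subject decomposition, followed by paired
t-tests on all condition pairs with Bonferroni adjustment
(p·m, capped at 1, m = pairs actually tested). A matrix with no condition
or residual variance beyond floating-point noise is flagged degenerate and
reported as p = 1 rather than an unstable F ratio.

## What the synthetic data emulate — and what they do not

`generate_mosaic()` produces jittered lattices: hexagonal packing (the
natural arrangement of a healthy cone mosaic) at a spacing set by the
target density, with isotropic Gaussian jitter (default 10% of spacing)
and out-of-bounds points dropped. `simulate_annotator()` has exactly three
error modes: independent Bernoulli misses, Poisson-count spurious marks
placed uniformly outside a half-spacing exclusion radius of true cones
(so a "false" mark cannot silently absorb into a true match), and Gaussian
localisation jitter clamped into the ROI. `generate_study()` composes
these into a multi-subject dataset: per-subject axial lengths N(23.71,
0.98²) mm, 5–16 ROIs per subject, square ROI sides N(70, 22²) µm,
across-ROI densities log-normal with natural-scale mean 30,600 and SD
14,200 cones/mm², eccentricities uniform on 135–2210 µm. These defaults
are the study conditions the package is validated under; the three default
graders' noise levels (miss 6–12%, false 16–23%, 1 µm jitter) bracket
reported experienced-human performance.

Three generator choices are worth recording. ROI sides are floored at 4.5
lattice spacings of the drawn density, so every ROI supports bound Voronoi
cells for every noisy annotator — without this, the rare low-density/small
ROI draw has no interior cell and the density stage cannot run, a
configuration a human analyst would never have cropped in the first place.
Sides, axial lengths and eccentricities are quantised (nm / 0.1 µm
precision) so the plain-text manifest represents them exactly and
regeneration is byte-identical. And density is *not* functionally tied to
eccentricity: the eccentricity column is carried as metadata only, because
the emulated study reports a range, not a density profile.

Equally important is what passing closed-loop tests does **not** show.
Real CHM mosaics have atrophic gaps, eccentricity gradients and spatially
correlated grader behaviour (a blurry patch is hard for everyone); the
generator has none of these, and real grader error is not three
independent processes. Closed-loop recovery therefore validates the
*pipeline arithmetic* — that the matching, density and agreement stages
measure what they claim on data with known truth — not the magnitude of
human agreement on patient images. Two systematic effects visible in the
closed loop are expected and documented: the adaptive threshold clips the
extreme jitter tail (see above), and at high miss rates recovered TPR
exceeds 1 − miss because spurious marks near a missed cone's location can
be matched to it. Both shrink into the noise at grader-like parameter
levels, where recovered mean TPR/FPR land within 0.02 of their targets
over ~200 ROIs.

## Problem sizes and determinism

The bundled tests and the acceptance script run entirely on generated
data: a full study of ~17 subjects / ~150–250 ROIs at these densities has
~100–300 cones per ROI, for which matching is a few milliseconds and the
Voronoi stage tens of milliseconds per annotator — a complete closed-loop
study runs in about two minutes on one core, and the test suite in under
two minutes. Every stochastic step takes an explicit integer seed
(sub-seeds for per-ROI draws are themselves drawn from the master seed),
so studies regenerate byte-identically and pipeline reruns are
reproducible modulo nothing.

## Known limitations

- The axial-length scale correction is linear by convention; users with
  full biometry should compute their own µm/px and bypass it.
- The multi-grader clustering is one deterministic resolution of a
  constraint-satisfaction problem the field leaves underspecified; other
  valid resolutions can differ on pathological configurations.
- Bound-cell classification treats boundary-touching vertices as inside;
  with coordinates quantised coarser than ~1e-9 µm of the border the flag
  can differ from a strict-interior convention.
- The ICC's CI assumes the usual normal-theory two-way model; heavily
  skewed densities may warrant transforming before `icc()`.
- `density_cov()` and the agreement summaries report across-ROI
  statistics; they do not model subject-level clustering of ROIs.
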