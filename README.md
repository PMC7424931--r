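# coneagree

Agreement analysis for cone photoreceptor mosaic annotations.

Adaptive-optics scanning laser ophthalmoscopy (AOSLO) resolves individual
cone photoreceptors in the living retina, and cone density is a central
structural endpoint in inherited retinal degenerations. Cone positions are
still mostly marked by human graders clicking on cell centres, so anyone
planning a longitudinal study needs to know how repeatable one grader is,
how reliable several graders are relative to each other, and how an
automated detector compares to either. `coneagree` implements the standard
analysis chain for those questions, working purely with point coordinates
(it never touches image data):

- **Adaptive matching threshold.** Selections from the annotators being
  compared are pooled into one *master list*; for every point the distance
  to its nearest other point is computed, and the matching threshold is
  `mean + 2 SD` of those nearest-neighbour distances. Two selections closer
  than the threshold may mark the same cone.
- **One-to-one matching and multi-grader clustering.** Candidate pairs are
  accepted greedily in ascending distance order (closest first, strictly
  one-to-one); with three or more graders, selections are agglomerated into
  clusters containing at most one selection per grader.
- **Agreement rates.** With one annotator as ground truth, a matched pair is
  a true positive; unmatched ground-truth cones are false negatives and
  unmatched comparison marks false positives. The package reports

  ```
  TPR  = N_TP / N_ground_truth
  FPR  = N_FP / N_comparison
  Dice = 2 N_TP / (N_ground_truth + N_comparison)
  ```

  and rotates the ground-truth role through all annotators.
- **Bound cone density.** Each annotator's mosaic is Voronoi-tessellated;
  cones whose cells are closed polygons lying entirely inside the region of
  interest (ROI) are *bound*, and density is `n_bound / sum(bound areas)` in
  cones/mm², which removes boundary bias.
- **Density agreement statistics.** Bland–Altman bias and 1.96 SD limits of
  agreement (log10-transformed automatically when the raw differences fail a
  Shapiro–Wilk normality test), two-way random-effects absolute-agreement
  single-measure ICC(2,1) with a 95% CI and Cicchetti qualitative band,
  repeated-measures one-way ANOVA with Bonferroni-corrected post hoc paired
  t-tests, and the per-ROI coefficient of variation of density.
- **Synthetic studies.** A generator for jittered hexagonal/square cone
  mosaics at a target density and a three-parameter annotator noise model
  (miss rate, false-mark fraction, localisation jitter), so the entire
  pipeline can be validated closed-loop against known ground truth.

## Worked example

Simulate one 70 µm ROI at 32,000 cones/mm², regrade it with grader-like
noise (6% misses, 18% spurious marks, 1 µm localisation jitter), and measure
agreement and density:

```r
library(coneagree)

roi <- roi_meta("P08", "r01", width_um = 70, height_um = 70,
                scale_um_per_px = scale_factor(25.23, 24, 0.45),
                axial_length_mm = 25.23, eccentricity_um = 450,
                meridian = "nasal")
truth   <- generate_mosaic(roi, 32000, "hexagonal", jitter_sd_um = 0.6, seed = 11)
regrade <- simulate_annotator(truth, miss_rate = 0.06, false_rate = 0.18,
                              localization_sd_um = 1, seed = 12,
                              annotator = "regrade")

(thr <- match_threshold(list(truth, regrade)))
#> <threshold_stats> mean NN 1.4373 um, SD 0.8757 um, threshold 3.1888 um (n = 311)

pm <- match_pairwise(truth, regrade, thr)
agreement_rates(confusion_from_match(pm))
#> <agreement_rates> TPR 0.9580, FPR 0.1845, Dice 0.8810

bound_density(truth)
#> <bound_density> 99 bound cones / 3100.5 um2 = 31930 cones/mm2
bound_density(regrade)
#> <bound_density> 124 bound cones / 3327.8 um2 = 37262 cones/mm2
```

The pooled master list puts the matching threshold at 3.19 µm for this ROI.
The regrading recovers 95.8% of the true cones; 18.5% of its marks have no
true counterpart, and the extra marks push its bound density up by about
17% — exactly the kind of asymmetry the density agreement statistics
(Bland–Altman, ICC) are there to quantify.

Whole studies are driven by `run_pipeline()` (or the thin wrapper in
`inst/scripts/coneagree.R`):

```r
run_pipeline(list(mode = "full", seed = 1, output_dir = "out",
                  study = list(n_subjects = 5)))
```

which writes per-ROI thresholds, matched pairs, agreement and density
tables, their summaries, and a statistics report (ICC, ANOVA,
Bland–Altman) as delimited text under `out/`.

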