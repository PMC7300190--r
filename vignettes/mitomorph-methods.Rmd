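---
title: "Quantifying mitochondrial network morphology and differential protein abundance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial network morphology and differential protein abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomorph)
```

## Scope and model

`mitomorph` implements two analysis arms that share one question — what does
loss of the Parkin ubiquitin ligase do to mitochondria in patient
fibroblasts? — but operate on different data.

The **imaging arm** quantifies the morphology of the mitochondrial network in
fluorescence micrographs across a balanced two-factor design: genotype
(control vs. *PARK2*-mutant) crossed with treatment (vehicle vs. the
protonophore CCCP, which depolarizes mitochondria and fragments the network).
Per field of view the pipeline is: spatial calibration, unsharp-mask
sharpening of every z-plane, Huang automatic thresholding to a binary mask,
removal of aberrantly detected objects, and per-object measurement of nine
shape descriptors (area, perimeter, major/minor axis, angle, aspect ratio,
circularity, roundness, solidity). The statistic of interest is
distributional: for each field of view, the two-sample Kolmogorov–Smirnov
distance between its particle-value distribution and the pooled distribution
of all control/vehicle fields. Those distances then enter a balanced two-way
fixed-effects ANOVA with interaction. Skeleton metrics (branches, junctions,
individuals, networks, mean branch length, footprint) describe the untreated
network's connectivity and are compared between genotypes with the Wilcoxon
rank-sum test. A separate marker arm measures a second channel (e.g. a
fission factor) inside the mitochondrial area defined by IsoData thresholding
of the reference channel, normalized per square micrometre.

The **proteomics arm** takes label-free quantification tables — per-protein
log2(patient/control) ratios over technical replicates with a variance — and
applies the post-acquisition workflow: isoform collapse to root accessions
(medians of ratio and variance), a detection rule (at least 2 of 3
replicates), a fold-change rule (at least 30% change, i.e.
|log2 ratio| ≥ |log2 1.30| = 0.3785…, displayed as 0.38), and a
summary-statistic significance test. Proteins detected in only one condition
("uniques") carry no ratio; they bypass the ratio and significance rules but
must satisfy the detection rule, and they are excluded from the volcano table
and from the ranked list. The ranked list (log2 ratio, descending) feeds a
pre-ranked gene-set enrichment engine with user-supplied sets.

## The synthetic-data generator

Neither arm can be exercised against the study's raw data at desk scale, so
every stage runs against simulated inputs with known ground truth.

**Images.** A field contains `n_objects` mitochondria-like objects:
*filaments* are spline-smoothed bounded-curvature random walks of
normally distributed length (default 5 ± 1.5 µm) rendered ~0.4 µm wide,
optionally with one side branch (probability 0.3); *fragments* are filled
ellipses (default 0.9 × 0.55 µm axes). An object is a fragment with
probability `fragment_fraction` — this is the dial the depolarization
treatment moves (defaults: 0.2 at baseline, 0.8 under CCCP, in both
genotypes, mirroring the direction of the study's finding that treatment and
not genotype drives morphology). The clean rendering is blurred with a
Gaussian point-spread function (σ = 0.15 µm at 0.1 µm/px) and shot noise is
Poisson on `background + photon_scale · signal`; the truth mask is the
pre-blur rendering. Z-stacks reuse the same object placement with per-slice
Gaussian z-weighting, matching an analysis that treats each plane's mask
separately. The marker channel multiplies the mitochondrial signal by
`marker_enrichment` over the same background, so a planted enrichment is
recovered as a known ratio of marker-per-area records. What the simulator
does *not* model: 3D point-spread functions, photobleaching, read noise,
cell boundaries, or spatially varying background — so green tests certify
the operators and the statistical machinery, not robustness to every
property of real micrographs.

A companion generator, `simulate_particle_study()`, draws particle
descriptor values directly from condition-level beta mixtures (fragments
high circularity, filaments low), skipping rendering. Calibration
experiments that need hundreds of simulated studies (type-I error, power)
use this distribution-level twin; the rendered-image path is exercised
end-to-end at small study sizes. This split is a deliberate design: the
KS + ANOVA machinery is identical in both paths, and rendering 100 fields
per study for hundreds of studies would add hours of compute without
changing what the calibration measures.

**LFQ tables.** Each protein's replicate log2 ratios are truth + Gaussian
noise with sd `replicate_cv / ln 2`; unchanged proteins have truth 0,
changed ones ± `effect_size_log2` with random sign; per-replicate
missingness is Bernoulli (default 0.05, reflecting the high detection
reproducibility of technical replicates in data-independent acquisition);
uniques are all-missing in one condition; isoform groups append `-n`
suffixed rows sharing the root's truth. Defaults (650 proteins, 30%
changed, 5% unique) echo the scale of a mitochondrial-fraction experiment.

## Numerical conventions that matter

**Perimeter.** The perimeter estimator is a closed 8-connected boundary
walk through boundary pixel centers: straight steps count 1, diagonal steps
√2, no corner-smoothing correction; an isolated pixel takes the unit-square
value 4. Under this convention a 10×10 px square measures 36 px and a
rasterized disk's circularity comes out near 0.91 (the chain overestimates
a smooth circle's perimeter by ~5%, and circularity is quadratic in that
bias). The reference particle-analysis tool applies an undocumented
corner-smoothing correction and reports slightly different values; we chose
the plain walk because it is exactly testable and document the divergence
rather than chase it. Circularity, roundness and solidity are capped at 1.

**Ellipse fit.** Axes come from the central second moments of the pixel
coordinates with the 1/12 per-pixel-square correction (which also keeps
single-pixel and collinear objects non-degenerate), rescaled so the ellipse
area equals the pixel area; the angle is reported in [0, 180) degrees
against the image x-axis with y up.

**Thresholds.** Both automatic thresholds operate on a 256-bin histogram;
real-valued images are min–max binned first. Huang minimizes the
fuzzy-entropy criterion by exhaustive scan; when a plateau of candidates
ties (fully separated histograms), the plateau's middle is returned rather
than an arbitrary end. IsoData iterates the intermeans map from the global
mean until a fixed point, with cycle detection. Foreground is strictly
greater than the threshold — one convention, fixed and tested. Cleanup
removes 8-connected components below `min_area_px` (default 10; the source
text never states its value, so it is exposed as configuration and recorded
in provenance) and optionally border-touching components.

**Skeletons.** Zhang–Suen thinning; the classic scheme deletes isolated
2×2 blocks entirely, so any source component that loses all pixels is
restored as its centroid-nearest pixel, keeping the component count exact.
Junction pixels are those with more than two 8-neighbors; adjacent junction
pixels merge into one node for branch tracing while the raw pixel count is
reported alongside (both are useful: the pixel count matches the published
definition, the node count drives tracing). Branch tracing visits neighbors
in a fixed scan order, so counts are reproducible under ties. "Mean network
size" is interpreted as mean branches per network — the source never defines
it formally, and this is stated in the output documentation as an
interpretation. Stacks are max-projected before skeletonization because the
published skeleton metrics are per-sample scalars.

**KS distances.** Computed on raw particle values (the two-sample statistic
is defined on empirical CDFs; kernel densities are for plots only, which is
also why the log transform applied to circularity for display provably does
not change any distance). The reference pool is every particle from
control/vehicle fields; by default a pool member's own particles are left
out of its reference (`leave_one_out = TRUE`) to avoid self-comparison
bias — comparing a sample against a pool containing itself shrinks its
distance toward zero. The literal-mimicry toggle is preserved. All
distances enter the ANOVA; we do not pre-filter distances by their own
significance, because selecting responses by significance before testing
them is statistically indefensible, and per-sample KS p-values are reported
alongside instead. The distance unit defaults to the field of view (the
densities are computed per field); subject-level pooling is available.

**ANOVA.** The balanced closed form (factor, factor, interaction, residual
sums of squares from cell means) with F against the residual mean square.
The designs this package builds are balanced by construction, so unbalanced
input is an explicit error rather than a silently different hypothesis
test; a completely constant response is flagged and reports NaN F. The
closed form is verified against the linear-model projection in the test
suite to 1e-8.

**Wilcoxon.** Exact two-sided p by enumeration when n + m ≤ 12 without
ties, otherwise the normal approximation with continuity and tie
correction — matching the reference implementation, which serves as the
oracle in tests.

**Summary p-values.** The only published description is that p is computed
"from variance, ratio, and sample size"; the canonical such test is the
one-sample t on the log2 ratio, `t = ratio / sqrt(variance / n)` with
`n − 1` degrees of freedom, and that is what is implemented, with n the
number of detected replicates (the alternative, fixed n = 3, is a
configuration away via the table's `n_detected` column). Zero variance is
flagged rather than silently producing infinities. The significance level
of the original software's call is not published; `alpha` is therefore a
required, recorded parameter (0.05 throughout the analysis scripts).

**Enrichment.** The running-sum statistic weights hits by |metric|
(exponent 1) normalized by the hit-weight total, and misses by
−1/(N − N_hit). Because the running sum is linear between hits, only the
values immediately at and before hit positions can be extrema, so each
evaluation is O(k log k) in the set size rather than O(N); the observed ES
is bit-identical to an independent implementation (`fgsea::calcGseaStat`)
in the tests. The null is gene-label permutation (default 10,000
permutations), the p-value two-sided with the +1 correction, adjustment by
Benjamini–Hochberg. Gene-label permutation tests a different null than
sample permutation; with user-supplied sets and no replicate-level data it
is the appropriate and stated choice.

## Problem sizes and calibration results

The test suite and the acceptance script size their simulations to finish
comfortably on one CPU: null calibration of the KS + ANOVA procedure uses
400 simulated studies of the full published design (2 × 2 cells, 5 subjects
per group, 5 fields per sample) via the distribution-level generator; power
uses 60–100 studies with the planted CCCP fragmentation; proteomic recovery
uses 500-protein tables; rendered-image tests use 96–192 px fields with
8–20 objects. Under those conditions the measured behavior is: type-I error
of both factors within [0.02, 0.08] at α = 0.05; treatment-factor power ≈ 1
with the mutation factor quiet (the planted configuration); differential
filter sensitivity ≥ 0.95 at effect 2.0 log2 / cv 0.1 / n = 3 with a
false-positive rate far below α; segmentation Jaccard overlap with the
rendered truth mask ≈ 0.8; a planted 2× marker enrichment recovered within
10%. Every one of those numbers is recomputed, not quoted, by
`scripts/acceptance.R` and the acceptance tests.

## Known limitations

- The perimeter (hence circularity) convention differs by a few percent
  from corner-smoothed estimators; comparisons across tools should compare
  distributions, not absolute descriptor values.
- No 3D morphometrics: stacks are analyzed per plane (particles) or after
  max projection (skeletons, marker area).
- The balanced-only ANOVA refuses unbalanced designs rather than switching
  sum-of-squares types.
- Gene sets must be supplied by the user; no pathway database is bundled or
  fetched.
- The simulator's noise model is Poisson-only and its objects are 2D; tests
  against it bound algorithmic correctness, not instrument realism.
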