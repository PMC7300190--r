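# mitomorph

Quantitative analysis of mitochondrial network morphology from fluorescence
microscopy, plus the label-free quantitative (LFQ) proteomics
differential-abundance workflow, for studies of Parkin-pathway (*PARK2*)
fibroblasts — or any balanced two-group × two-treatment imaging design with a
patient/control proteome comparison. Everything runs against a bundled
synthetic-data generator with planted ground truth, so the full analysis is
reproducible without any raw study data.

## What it computes

**Imaging arm.** Per field of view: unsharp-mask sharpening, Huang automatic
thresholding, small-object cleanup, then the nine particle shape descriptors
(Area, Perimeter, Major/Minor axis, Angle, Aspect ratio, Circularity
`4πA/P²`, Roundness `4A/(πM²)`, Solidity `A/A_hull`) per z-plane, and
skeleton metrics (branches, junction pixels, individuals, networks, mean
branch length, footprint) after Zhang–Suen thinning. The study-level
statistic is the two-sample Kolmogorov–Smirnov distance

> D = sup_x | F̂_sample(x) − F̂_reference(x) |

of each field's particle-value distribution against the pooled control/DMSO
reference, followed by a balanced two-way ANOVA (mutation × treatment, with
interaction) of the distances, and Wilcoxon rank-sum comparisons of the
untreated skeleton metrics. A marker arm quantifies a second channel per
square micrometre of mitochondrial area (IsoData threshold of the reference
channel) and whole-image fluorescence normalized by cell count or area.

**Proteomics arm.** Isoform collapse to root accessions (medians), the
2-of-3 replicate detection rule, the 30% fold-change rule
(|log2 ratio| ≥ |log2 1.30| = 0.38), a summary-statistic one-sample t test
(`t = ratio/√(variance/n)`, df = n−1), volcano tables, a log2(P/C)-ranked
gene list (condition-unique proteins excluded), and pre-ranked gene-set
enrichment by weighted running sum with a gene-label permutation null and
Benjamini–Hochberg adjustment.

## Worked example

Simulate a small study with fragmentation planted under CCCP treatment, run
the morphology pipeline, and read the treatment effect off the ANOVA of the
KS distances:

```r
library(mitomorph)

base <- image_sim_config(image_shape = c(128, 128), n_objects = 14,
                         fragment_fraction = 0.1)
design <- study_design(base, n_subjects_per_group = 2, n_fov_per_sample = 2,
                       overrides = list(CTRL.CCCP = list(fragment_fraction = 0.9),
                                        MUT.CCCP  = list(fragment_fraction = 0.9)),
                       seed = 8)
pop <- simulate_population(design)
res <- run_morphology_pipeline(pop)
res$anova$circularity
#> Balanced two-way ANOVA 
#>                term        SS df        MS        F         p
#>            mutation 0.0009161  1 0.0009161  0.06888 7.974e-01
#>           treatment 0.5509576  1 0.5509576 41.42615 3.225e-05
#>  mutation:treatment 0.0007736  1 0.0007736  0.05817 8.135e-01
#>           Residuals 0.1595971 12 0.0132998       NA        NA
```

Treatment dominates (p ≈ 3e-5) while genotype and interaction are quiet —
the planted configuration. At the full published design (5 subjects/group,
5 fields/sample; `analysis/01_simulate_study.R`) the same readout gives
treatment p ≈ 8e-25 for circularity with mutation p ≈ 0.74.

The proteomics arm on a simulated 650-protein mitochondrial-fraction table
(`analysis/04_proteomics.R`) prints the filter chain:

```
 n_input  n_after_replicate_filter  n_after_fc_filter  n_after_p_filter  n_unique_included
     650                       648                227               211                 32
thresholds: >=2 replicates, |log2 ratio| >= 0.3785, p <= 0.05
altered fraction in the simulated mito table: 32.5%
```

Each count is the number of proteins surviving that filter stage; the
retained table carries the summary p-values and unique-protein flags.

## Analysis workflow

Numbered drivers under `analysis/` reproduce the whole study on synthetic
data, writing tables under `results/`:

1. `01_simulate_study.R` — render the 2×2×5×5 imaging study and the LFQ table
2. `02_morphology_pipeline.R` — segmentation, particles, skeletons, KS + ANOVA
3. `03_densities_and_markers.R` — density grids; marker-per-area ANOVA
4. `04_proteomics.R` — differential filters, volcano, ranked list
5. `05_enrichment.R` — pre-ranked enrichment (10,000 permutations)

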