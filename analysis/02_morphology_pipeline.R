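#!/usr/bin/env Rscript
# Segment every simulated field (unsharp mask -> Huang threshold -> small
# object cleanup), measure the nine particle shape descriptors per z-plane,
# and summarize each field's skeleton (branches, junctions, individuals,
# networks, mean branch length, footprint). Then compute per-field KS
# distances to the pooled CTRL/DMSO particle distribution and the two-way
# ANOVA (mutation x treatment) of those distances for every parameter,
# plus genotype Wilcoxon comparisons of the untreated skeleton metrics.
# Requires analysis/01_simulate_study.R to have run.

library(mitomorph)

manifest <- "results/data/manifest.csv"
if (!file.exists(manifest)) stop("run analysis/01_simulate_study.R first")

res <- run_morphology_pipeline(manifest, out_dir = "results/morphology")

message(nrow(res$particles), " particles measured across ",
        length(unique(paste(res$particles$subject, res$particles$treatment,
                            res$particles$fov))), " fields")
for (param in c("circularity", "roundness", "solidity")) {
  tab <- res$anova[[param]]$table
  message(sprintf("%-12s treatment p = %.3g | mutation p = %.3g",
                  param, tab$p[2], tab$p[1]))
}
message("skeleton Wilcoxon (CTRL vs MUT, DMSO): min p = ",
        signif(min(res$wilcoxon$p), 3))
message("outputs under results/morphology/")
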