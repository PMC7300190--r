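#!/usr/bin/env Rscript
# Simulate the study inputs: a balanced 2-genotype x 2-treatment imaging
# study (5 subjects per group, 5 fields of view per sample, fragmentation
# planted under CCCP in both genotypes) and a mitochondrial-fraction LFQ
# table with planted abundance changes. Images go to results/data/ as
# 16-bit TIFFs with a metadata manifest; the quant table as CSV.
#
# At the published field count this renders 100 two-channel fields; the
# driver defaults to a reduced field size (192 px) to keep a laptop run in
# minutes. All seeds are fixed here.

library(mitomorph)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

base <- image_sim_config(image_shape = c(192L, 192L), n_objects = 20,
                         fragment_fraction = 0.2)
design <- study_design(base,
                       n_subjects_per_group = 5L, n_fov_per_sample = 5L,
                       overrides = list(CTRL.CCCP = list(fragment_fraction = 0.8),
                                        MUT.CCCP = list(fragment_fraction = 0.8)),
                       seed = 20260101L)
message("simulating ", 2 * 5 * 2 * 5, " two-channel fields...")
pop <- simulate_population(design)
md <- write_study(pop, file.path(out, "images"))
md$pixel_size_um <- base$pixel_size_um
write.csv(md, file.path(out, "manifest.csv"), row.names = FALSE)
message("wrote ", nrow(md), " image sets under ", file.path(out, "images"))

pcfg <- proteome_sim_config(n_proteins = 650L, frac_changed = 0.3,
                            effect_size_log2 = 1.0, replicate_cv = 0.1,
                            n_replicates = 3L, missing_prob = 0.05,
                            frac_unique = 0.05, n_isoform_groups = 20L,
                            seed = 20260102L)
quant <- simulate_proteome_table(pcfg)
write.csv(quant, file.path(out, "quant_mito.csv"), row.names = FALSE)
message("wrote LFQ table: ", nrow(quant), " rows (",
        sum(quant$truth_status == "changed"), " planted changes, ",
        sum(quant$truth_status == "unique"), " uniques)")
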