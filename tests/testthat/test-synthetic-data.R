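# Synthetic microscopy and LFQ generators: determinism, truth consistency,
# planted effects.

test_that("image simulation is seed-deterministic and validates its config", {
  cfg <- image_sim_config(image_shape = c(96, 96), n_objects = 8, seed = 7)
  a <- simulate_mito_image(cfg)
  b <- simulate_mito_image(cfg)
  expect_identical(a$mito$pixels, b$mito$pixels)
  expect_identical(a$marker$pixels, b$marker$pixels)
  expect_identical(a$truth_mask, b$truth_mask)
  expect_error(image_sim_config(fragment_fraction = 1.2), "fragment_fraction")
  expect_error(image_sim_config(image_shape = c(-4, 64)), "image_shape")
  expect_error(image_sim_config(psf_sigma_um = 0), "psf_sigma_um")
})

test_that("with zero photon scale both channels are pure background noise", {
  cfg <- image_sim_config(image_shape = c(128, 128), photon_scale = 0,
                          background_level = 6, seed = 3)
  sim <- simulate_mito_image(cfg)
  for (ch in c("mito", "marker")) {
    px <- sim[[ch]]$pixels
    expect_equal(mean(px), 6, tolerance = 0.15)      # Poisson(6) mean
    expect_equal(var(as.vector(px)), 6, tolerance = 0.5)
    # no object structure: intensity inside vs outside the truth mask agrees
    expect_equal(mean(px[sim$truth_mask]), mean(px[!sim$truth_mask]),
                 tolerance = 0.3)
  }
})

test_that("fragment_fraction = 1 yields only fragments, 0 only filaments", {
  cfg1 <- image_sim_config(image_shape = c(96, 96), n_objects = 20,
                           fragment_fraction = 1, seed = 5)
  expect_equal(sum(simulate_mito_image(cfg1)$truth_table$type == "fragment"), 20L)
  cfg0 <- image_sim_config(image_shape = c(96, 96), n_objects = 12,
                           fragment_fraction = 0, seed = 5)
  expect_equal(sum(simulate_mito_image(cfg0)$truth_table$type == "filament"), 12L)
})

test_that("truth table objects are consistent with the truth mask", {
  cfg <- image_sim_config(image_shape = c(128, 128), n_objects = 15, seed = 9)
  sim <- simulate_mito_image(cfg)
  tt <- sim$truth_table
  expect_equal(nrow(tt), 15L)
  expect_true(all(tt$n_px > 0))
  # union area <= sum of object areas (overlaps), >= largest object
  expect_lte(sum(sim$truth_mask), sum(tt$n_px))
  expect_gte(sum(sim$truth_mask), max(tt$n_px))
})

test_that("study population is balanced and carries planted overrides only where asked", {
  base <- image_sim_config(image_shape = c(64, 64), n_objects = 6,
                           fragment_fraction = 0)
  des <- study_design(base, n_subjects_per_group = 2, n_fov_per_sample = 2,
                      overrides = list(MUT.DMSO = list(fragment_fraction = 1)),
                      seed = 11)
  pop <- simulate_population(des)
  expect_equal(length(pop$images), 2 * 2 * 2 * 2)
  expect_equal(nrow(pop$metadata), 16L)
  md <- pop$metadata
  frag_counts <- vapply(seq_len(nrow(md)), function(i)
    sum(pop$images[[md$index[i]]]$truth_table$type == "fragment"), numeric(1))
  target <- md$group == "MUT" & md$treatment == "DMSO"
  expect_true(all(frag_counts[target] == 6))
  expect_true(all(frag_counts[!target] == 0))
  expect_error(study_design(base, n_subjects_per_group = 0), "at least one")
  expect_error(study_design(base, overrides = list(BAD.CELL = list())),
               "GROUP.TREATMENT")
})

test_that("TIFF round trip preserves photon counts and metadata", {
  dir <- withr::local_tempdir()
  base <- image_sim_config(image_shape = c(48, 48), n_objects = 4, n_slices = 2)
  des <- study_design(base, n_subjects_per_group = 1, n_fov_per_sample = 1,
                      seed = 2)
  pop <- simulate_population(des)
  md <- write_study(pop, dir)
  expect_true(all(file.exists(md$path_mito)))
  img <- read_calibrated_tiff(md$path_mito[1], 0.1, "mito")
  expect_equal(img$pixels, pop$images[[md$index[1]]]$mito$pixels,
               tolerance = 1e-9)
  truth <- read.csv(file.path(dir, "truth.csv"))
  expect_true(all(c("subject", "treatment", "fov", "type") %in% names(truth)))
})

test_that("proteome tables are reproducible with coherent truth labels", {
  cfg <- proteome_sim_config(n_proteins = 200, frac_changed = 0.2,
                             frac_unique = 0.1, seed = 13)
  a <- simulate_proteome_table(cfg)
  b <- simulate_proteome_table(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 200L)
  expect_equal(sum(a$truth_status == "unique"), 20L)
  expect_equal(sum(a$truth_status == "changed"), 40L)
  # uniques carry no ratios; changed truth is +/- effect size
  expect_true(all(is.na(a$log2_ratio[a$truth_status == "unique"])))
  expect_true(all(abs(a$truth_log2[a$truth_status == "changed"]) == 1))
  expect_true(all(a$truth_log2[a$truth_status == "unchanged"] == 0))
  expect_true(all(a$n_detected <= 3))
  expect_error(proteome_sim_config(frac_changed = 0.7, frac_unique = 0.5),
               "exceed 1")
  expect_error(proteome_sim_config(n_replicates = 1), "n_replicates")
})

test_that("null tables produce ~alpha-calibrated summary p-values and few filter passes", {
  cfg <- proteome_sim_config(n_proteins = 1000, frac_changed = 0,
                             frac_unique = 0, missing_prob = 0, seed = 17)
  tab <- simulate_proteome_table(cfg)
  p <- summary_pvalue(tab$log2_ratio, tab$variance, tab$n_detected)
  # the one-sample t on 3 replicates of pure noise is uniform: type-I ~ alpha
  expect_gt(mean(p <= 0.05), 0.03)
  expect_lt(mean(p <= 0.05), 0.07)
  # combined fold-change + significance filter passes at most the t-test rate
  d <- filter_differential(tab, alpha = 0.05)
  expect_lte(d$counts[["n_after_p_filter"]], sum(p <= 0.05))
})

test_that("strong planted effects are recovered almost completely", {
  cfg <- proteome_sim_config(n_proteins = 500, frac_changed = 0.2,
                             effect_size_log2 = 2, replicate_cv = 0.05,
                             missing_prob = 0, frac_unique = 0, seed = 19)
  tab <- simulate_proteome_table(cfg)
  d <- filter_differential(tab, alpha = 0.05)
  changed_in <- sum(tab$truth_status == "changed")
  changed_out <- sum(d$table$truth_status == "changed")
  expect_gte(changed_out / changed_in, 0.95)
})

test_that("isoform groups expand rows and collapse back to roots", {
  cfg <- proteome_sim_config(n_proteins = 50, n_isoform_groups = 10,
                             isoforms_per_group = 3, frac_unique = 0, seed = 23)
  tab <- simulate_proteome_table(cfg)
  expect_equal(nrow(tab), 50 + 10 * 2)
  expect_equal(nrow(collapse_isoforms(tab)), 50L)
})
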