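# Isoform collapse, summary p-values, differential filters, volcano table,
# ranked list.

test_that("isoform collapse takes medians and is idempotent", {
  tab <- data.frame(accession = c("P1", "P1-2", "P1-3", "Q2"),
                    log2_ratio = c(0.5, 1.0, 1.5, 0.2),
                    variance = c(0.01, 0.02, 0.03, 0.05),
                    n_detected = c(3, 2, 3, 3))
  col <- collapse_isoforms(tab)
  expect_equal(nrow(col), 2L)
  expect_equal(col$log2_ratio[col$accession == "P1"], 1.0)
  expect_equal(col$variance[col$accession == "P1"], 0.02)
  expect_equal(col$n_detected[col$accession == "P1"], 3)
  # even isoform count: mean of the middle pair
  tab2 <- data.frame(accession = c("P9", "P9-2"), log2_ratio = c(0.2, 0.6),
                     variance = c(0.1, 0.3), n_detected = c(2, 3))
  expect_equal(collapse_isoforms(tab2)$log2_ratio, 0.4)
  # no suffixes: unchanged; collapsing twice equals once
  plain <- data.frame(accession = c("A1", "B2"), log2_ratio = c(1, 2),
                      variance = c(0.1, 0.1), n_detected = c(3, 3))
  expect_equal(collapse_isoforms(plain), plain)
  expect_equal(collapse_isoforms(col), col)
})

test_that("summary p-value is a two-sided one-sample t from summary statistics", {
  expect_equal(as.numeric(summary_pvalue(0, 0.02, 3)), 1)
  # independent CDF evaluation
  t_stat <- 0.38 / sqrt(0.01 / 3)
  expect_equal(as.numeric(summary_pvalue(0.38, 0.01, 3)),
               2 * (1 - pt(t_stat, df = 2)), tolerance = 1e-6)
  # sign invariance and monotonicity in |ratio|
  expect_equal(summary_pvalue(0.7, 0.05, 3), summary_pvalue(-0.7, 0.05, 3))
  ps <- as.numeric(summary_pvalue(c(0.1, 0.5, 1, 2), 0.05, 3))
  expect_true(all(diff(ps) < 0))
  # zero variance flags; n < 2 errors
  p0 <- summary_pvalue(c(0.5, 0), c(0, 0), c(3, 3))
  expect_equal(as.numeric(p0), c(0, 1))
  expect_true(all(attr(p0, "zero_variance")))
  expect_error(summary_pvalue(0.5, 0.1, 1), "n must be")
})

test_that("differential filters apply the three rules with inclusive boundaries", {
  thr <- fc_threshold_log2()
  tab <- data.frame(
    accession = sprintf("P%d", 1:6),
    log2_ratio = c(1.2, -thr, 0.05, 2.0, NA, 0.5),
    variance = c(0.01, 0.001, 0.01, 1.5, NA, 0.02),
    n_detected = c(3, 3, 3, 3, 2, 1),
    uniqueness = c("none", "none", "none", "none", "patient_only", "none"))
  # by hand: P1 passes all; P2 exactly at threshold, passes (inclusive) with
  # tiny variance so p passes; P3 fails fold change; P4 passes fc but p too
  # large (variance 1.5, n 3 gives p ~ 0.1); P5 unique, 2 reps -> included;
  # P6 detected once -> excluded regardless of ratio
  d <- filter_differential(tab, min_detected = 2, alpha = 0.05)
  expect_setequal(d$table$accession, c("P1", "P2", "P5"))
  expect_equal(unname(d$counts["n_input"]), 6)
  expect_equal(unname(d$counts["n_unique_included"]), 1)
  expect_true(all(diff(d$counts[1:4]) <= 0))   # monotone filter chain
  expect_error(filter_differential(tab, fc_log2 = -0.1), "non-negative")
})

test_that("the displayed 0.38 threshold is the rounded exact 30% rule", {
  expect_equal(round(fc_threshold_log2(), 2), 0.38)
  expect_equal(fc_threshold_log2(), abs(log2(1.3)))
})

test_that("volcano table statuses match the filter thresholds", {
  tab <- data.frame(accession = c("A", "B", "C", "U1"),
                    log2_ratio = c(1, -1, 0.01, NA),
                    variance = c(0.01, 0.01, 0.01, NA),
                    n_detected = c(3, 3, 3, 3),
                    uniqueness = c("none", "none", "none", "patient_only"))
  v <- volcano_table(tab)
  expect_equal(nrow(v), 3L)        # uniques excluded
  expect_equal(v$status[v$accession == "A"], "up")
  expect_equal(v$status[v$accession == "B"], "down")
  expect_equal(v$status[v$accession == "C"], "ns")
  # all-null table: no up/down; p = 1 maps to -log10 p = 0
  tabn <- data.frame(accession = c("A", "B"), log2_ratio = c(0, 0),
                     variance = c(0.01, 0.01), n_detected = c(3, 3))
  vn <- volcano_table(tabn)
  expect_true(all(vn$status == "ns"))
  expect_equal(vn$neg_log10_p, c(0, 0))
})

test_that("volcano counts track planted truth on a simulated table", {
  cfg <- proteome_sim_config(n_proteins = 400, frac_changed = 0.25,
                             effect_size_log2 = 2, replicate_cv = 0.1,
                             missing_prob = 0, frac_unique = 0, seed = 29)
  tab <- simulate_proteome_table(cfg)
  v <- volcano_table(tab)
  n_hit <- sum(v$status != "ns")
  n_true <- sum(tab$truth_status == "changed")
  expect_equal(n_hit, n_true, tolerance = 0.05)
  up_truth <- sum(tab$truth_log2 > 0, na.rm = TRUE)
  expect_equal(sum(v$status == "up"), up_truth, tolerance = 0.06)
})

test_that("ranked list excludes uniques and sorts by metric with stable ties", {
  tab <- data.frame(accession = c("B", "A", "C", "U"),
                    log2_ratio = c(1, -1, 0, NA),
                    variance = rep(0.1, 4), n_detected = rep(3, 4),
                    uniqueness = c("none", "none", "none", "control_only"))
  rk <- ranked_list(tab)
  expect_equal(rk$id, c("B", "C", "A"))
  expect_equal(rk$metric, c(1, 0, -1))
  # ties break deterministically by accession
  tab2 <- data.frame(accession = c("Z", "M", "A"), log2_ratio = c(0.5, 0.5, 0.5),
                     variance = rep(0.1, 3), n_detected = rep(3, 3))
  expect_equal(ranked_list(tab2)$id, c("A", "M", "Z"))
  # permutation contract on a random table
  cfg <- proteome_sim_config(n_proteins = 100, frac_unique = 0.1, seed = 3)
  tabr <- simulate_proteome_table(cfg)
  rkr <- ranked_list(tabr)
  non_unique <- tabr$accession[tabr$uniqueness == "none" & !is.na(tabr$log2_ratio)]
  expect_setequal(rkr$id, non_unique)
  expect_false(is.unsorted(rev(rkr$metric)))
  expect_error(ranked_list(tab[4, ]), "empty")
})
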