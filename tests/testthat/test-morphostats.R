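# KS distances, kernel densities, balanced two-way ANOVA, Wilcoxon.

test_that("KS distance matches brute force, base R, and its boundary cases", {
  set.seed(3)
  x <- rnorm(83); y <- rnorm(61, 0.4)
  expect_equal(ks_distance(x, y), oracle_ks(x, y))
  expect_equal(ks_distance(x, y), unname(ks.test(x, y)$statistic))
  # tied data
  xt <- sample(rep(1:15, 6)); yt <- sample(rep(3:18, 5))
  expect_equal(ks_distance(xt, yt), oracle_ks(xt, yt))
  expect_equal(ks_distance(xt, yt),
               suppressWarnings(unname(ks.test(xt, yt)$statistic)))
  # identical samples and disjoint supports
  expect_equal(ks_distance(x, x), 0)
  expect_equal(ks_distance(1:10, 11:20), 1)
  expect_error(ks_distance(numeric(0), 1:3), "non-empty")
  # overlapping uniforms: closed-form sup = 0.5
  set.seed(4)
  expect_equal(ks_distance(runif(5000), runif(5000, 0.5, 1.5)), 0.5,
               tolerance = 0.03)
})

test_that("KS distance is invariant under strictly increasing transforms", {
  set.seed(7)
  for (i in 1:10) {
    x <- rexp(50 + i); y <- rexp(70, 1.4)
    d0 <- ks_distance(x, y)
    expect_identical(d0, ks_distance(log(x), log(y)))
    expect_identical(d0, ks_distance(exp(x), exp(y)))
    expect_identical(d0, ks_distance(x^3, y^3))
  }
})

test_that("density estimates integrate to one and find the mode", {
  set.seed(12)
  x <- rnorm(2000)
  d <- density_estimate(x)
  expect_equal(sum(diff(d$x) * (head(d$y, -1) + tail(d$y, -1)) / 2), 1,
               tolerance = 1e-3)
  expect_lt(abs(d$x[which.max(d$y)]), 0.1)
  # Silverman-type bandwidth rule
  expect_equal(d$bw, 0.9 * min(sd(x), IQR(x) / 1.34) * 2000^(-1 / 5))
  # log transform on positive data; errors on degenerate input
  dl <- density_estimate(rexp(500), transform = "log")
  expect_equal(sum(diff(dl$x) * (head(dl$y, -1) + tail(dl$y, -1)) / 2), 1,
               tolerance = 1e-3)
  expect_error(density_estimate(rep(3, 10)), "distinct")
  expect_error(density_estimate(c(-1, 2, 3), transform = "log"), "positive")
})

test_that("a pooled-reference unit compared to itself has zero distance", {
  df <- data.frame(subject = "C1", group = "CTRL", treatment = "DMSO",
                   fov = 1, circularity = rbeta(50, 2, 2))
  dt <- sample_distance_table(df, "circularity", leave_one_out = FALSE)
  expect_equal(dt$D, 0)
  expect_error(sample_distance_table(df, "nope"), "unknown parameter")
  dfo <- df; dfo$group <- "MUT"
  expect_error(sample_distance_table(dfo, "circularity"), "empty reference")
})

test_that("distance tables separate a planted fragmentation effect", {
  parts <- simulate_particle_study(seed = 101)
  dt <- sample_distance_table(parts, "circularity")
  expect_true(all(dt$D >= 0 & dt$D <= 1))
  m <- tapply(dt$D, paste(dt$group, dt$treatment), mean)
  expect_gt(m[["MUT CCCP"]], m[["CTRL DMSO"]])
  expect_gt(m[["CTRL CCCP"]], m[["CTRL DMSO"]])
  # 2x2x5 subjects x5 fov = 100 units
  expect_equal(nrow(dt), 100L)
  # leave-one-out shrinks the reference for pool members only
  in_pool <- dt$group == "CTRL" & dt$treatment == "DMSO"
  expect_true(all(dt$n_reference[in_pool] < max(dt$n_reference)))
})

test_that("balanced two-way ANOVA equals the linear-model projection oracle", {
  set.seed(31)
  for (i in 1:5) {
    a <- rep(c("CTRL", "MUT"), each = 10)
    b <- rep(rep(c("DMSO", "CCCP"), each = 5), 2)
    y <- rnorm(20, mean = 2 + 0.5 * (a == "MUT") * (i %% 2))
    fit <- two_way_anova(y, a, b, names_ab = c("mutation", "treatment"))
    oracle <- anova(lm(y ~ factor(a) * factor(b)))
    expect_equal(fit$table$SS, unname(oracle$`Sum Sq`), tolerance = 1e-8)
    expect_equal(fit$table$F[1:3], unname(oracle$`F value`[1:3]), tolerance = 1e-8)
    expect_equal(fit$table$p[1:3], unname(oracle$`Pr(>F)`[1:3]), tolerance = 1e-8)
    expect_equal(sum(fit$table$SS), fit$SS_total,
                 tolerance = 1e-9 * max(1, fit$SS_total))
    expect_equal(sum(fit$table$df), length(y) - 1)
  }
})

test_that("ANOVA handles degenerate, single-factor and invalid designs", {
  a <- rep(c("C", "M"), each = 6); b <- rep(rep(c("D", "K"), each = 3), 2)
  # all equal: zero SS, NaN F, flagged
  fit0 <- two_way_anova(rep(5, 12), a, b)
  expect_true(fit0$degenerate)
  expect_equal(fit0$table$SS, rep(0, 4), tolerance = 1e-20)
  expect_true(all(is.nan(fit0$table$F[1:3])))
  # response depends only on factor A: SS_B and SS_int vanish
  y <- ifelse(a == "C", 1, 3)
  fitA <- two_way_anova(y, a, b)
  expect_equal(fitA$table$SS[2], 0, tolerance = 1e-9)
  expect_equal(fitA$table$SS[3], 0, tolerance = 1e-9)
  # empty cell names the cell; unbalanced is an explicit error
  expect_error(two_way_anova(rnorm(9), rep(c("C", "M", "M"), 3),
                             rep(c("D", "D", "D"), 3)), "2 levels")
  a2 <- c("C", "C", "M", "M", "C"); b2 <- c("D", "K", "D", "K", "D")
  expect_error(two_way_anova(rnorm(5), a2, b2), "unbalanced")
  a3 <- c("C", "C", "M"); b3 <- c("D", "K", "D")
  expect_error(two_way_anova(rnorm(3), a3, b3), "empty design cell")
})

test_that("Wilcoxon rank-sum: exact enumeration and normal approximation", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p, 0.1)
  expect_equal(w$method, "exact")
  # identical sets: maximal tie, p ~ 1
  expect_gte(wilcoxon_rank_sum(1:5, 1:5)$p, 0.95)
  # exact path against base R across random small samples
  set.seed(41)
  for (i in 1:10) {
    x <- rnorm(sample(3:6, 1)); y <- rnorm(sample(3:6, 1))
    mine <- wilcoxon_rank_sum(x, y)
    base <- wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$p, base$p.value, tolerance = 1e-12)
    expect_equal(mine$U, unname(base$statistic))
  }
  # normal approximation with continuity and tie correction
  for (i in 1:5) {
    x <- sample(1:10, 25, replace = TRUE); y <- sample(2:12, 30, replace = TRUE)
    mine <- wilcoxon_rank_sum(x, y)
    base <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(mine$p, base$p.value, tolerance = 1e-10)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("the exact Wilcoxon null distribution sums to one and is uniform-ish", {
  # enumeration distribution over rank sums for n=4, m=5
  combs <- combn(9, 4)
  sums <- colSums(matrix(seq_len(9)[combs], nrow = 4))
  probs <- table(sums) / ncol(combs)
  expect_equal(sum(probs), 1)
  # p-values under the null are conservative-uniform: check mean ~ 0.5
  set.seed(51)
  ps <- replicate(400, wilcoxon_rank_sum(rnorm(30), rnorm(30))$p)
  expect_lt(suppressWarnings(ks.test(ps, "punif")$statistic), 0.08)
})
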