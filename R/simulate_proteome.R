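# Synthetic label-free quantification tables with planted ground truth.

#' Configuration for a simulated LFQ protein table
#'
#' Emulates a patient-vs-control label-free experiment with technical
#' replicates: per-protein log2(P/C) ratios equal to a planted truth (0 for
#' unchanged proteins, +/- `effect_size_log2` for changed ones) plus
#' replicate noise, per-replicate missingness, a fraction of proteins
#' detected in one condition only ("uniques"), and optional isoform groups
#' sharing a root accession.
#'
#' @param n_proteins Number of root proteins.
#' @param frac_changed Fraction with a planted abundance change.
#' @param effect_size_log2 Mean absolute log2 ratio of changed proteins.
#' @param replicate_cv Technical coefficient of variation on the linear
#'   scale; replicate log2 ratios get sd `replicate_cv / log(2)`.
#' @param n_replicates Technical replicates (>= 2).
#' @param missing_prob Per-replicate probability of a missing measurement.
#' @param frac_unique Fraction detected in only one condition.
#' @param n_isoform_groups Number of proteins that additionally carry
#'   isoform rows (suffix `-2`, `-3`, ...).
#' @param isoforms_per_group Rows per isoform group (>= 2).
#' @param seed Integer seed; reproducible.
#' @return Validated list of class `proteome_sim_config`.
#' @export
proteome_sim_config <- function(n_proteins = 650L, frac_changed = 0.3,
                                effect_size_log2 = 1.0, replicate_cv = 0.1,
                                n_replicates = 3L, missing_prob = 0.05,
                                frac_unique = 0.05, n_isoform_groups = 0L,
                                isoforms_per_group = 3L, seed = NULL) {
  cfg <- list(n_proteins = as.integer(n_proteins), frac_changed = frac_changed,
              effect_size_log2 = effect_size_log2, replicate_cv = replicate_cv,
              n_replicates = as.integer(n_replicates),
              missing_prob = missing_prob, frac_unique = frac_unique,
              n_isoform_groups = as.integer(n_isoform_groups),
              isoforms_per_group = as.integer(isoforms_per_group),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  for (p in c("frac_changed", "frac_unique", "missing_prob"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  if (cfg$frac_changed + cfg$frac_unique > 1)
    stop("frac_changed + frac_unique must not exceed 1")
  if (cfg$n_replicates < 2L) stop("n_replicates must be >= 2")
  if (cfg$replicate_cv <= 0 || cfg$effect_size_log2 < 0)
    stop("replicate_cv must be > 0 and effect_size_log2 >= 0")
  if (cfg$n_isoform_groups > cfg$n_proteins)
    stop("n_isoform_groups cannot exceed n_proteins")
  if (cfg$n_isoform_groups > 0 && cfg$isoforms_per_group < 2L)
    stop("isoform groups need >= 2 members")
  structure(cfg, class = "proteome_sim_config")
}

summarize_replicates <- function(rep_mat) {
  n_det <- rowSums(!is.na(rep_mat))
  log2_ratio <- apply(rep_mat, 1, stats::median, na.rm = TRUE)
  variance <- apply(rep_mat, 1, stats::var, na.rm = TRUE)
  log2_ratio[n_det == 0] <- NA_real_
  variance[n_det < 2] <- NA_real_
  list(n_detected = n_det, log2_ratio = log2_ratio, variance = variance)
}

#' Simulate an LFQ quantification table with truth labels
#'
#' @param config A [proteome_sim_config()].
#' @return Data.frame: `accession`, `fraction`, replicate columns
#'   `rep_1..rep_k` (log2 ratios, `NA` = not detected), `n_detected`,
#'   `log2_ratio` (median of detected replicates), `variance`, `uniqueness`
#'   (`none` / `patient_only` / `control_only`), and truth columns
#'   `truth_status` (`unchanged` / `changed` / `unique`), `truth_log2`.
#' @export
simulate_proteome_table <- function(config) {
  stopifnot(inherits(config, "proteome_sim_config"))
  with_seed(config$seed, {
    n <- config$n_proteins; k <- config$n_replicates
    n_uniq <- round(config$frac_unique * n)
    n_chg <- round(config$frac_changed * n)
    status <- sample(c(rep("unique", n_uniq), rep("changed", n_chg),
                       rep("unchanged", n - n_uniq - n_chg)))
    acc <- sprintf("SP%04d", seq_len(n))
    truth <- ifelse(status == "changed",
                    config$effect_size_log2 * sample(c(-1, 1), n, replace = TRUE),
                    0)
    truth[status == "unique"] <- NA_real_
    sd2 <- config$replicate_cv / log(2)
    build_rows <- function(accession, st, tr) {
      m <- length(accession)
      rep_mat <- matrix(tr, m, k) + matrix(stats::rnorm(m * k, 0, sd2), m, k)
      det <- matrix(stats::runif(m * k) >= config$missing_prob, m, k)
      rep_mat[!det] <- NA_real_
      rep_mat[st == "unique", ] <- NA_real_
      uniq_side <- ifelse(st == "unique",
                          sample(c("patient_only", "control_only"), m, replace = TRUE),
                          "none")
      # uniques: detection happens in their single condition; reuse the same
      # per-replicate detection draws for the 2-of-k rule
      n_det <- rowSums(det)
      s <- summarize_replicates(rep_mat)
      n_det[st != "unique"] <- s$n_detected[st != "unique"]
      df <- data.frame(accession = accession, fraction = "mito")
      colnames_rep <- sprintf("rep_%d", seq_len(k))
      for (j in seq_len(k)) df[[colnames_rep[j]]] <- rep_mat[, j]
      df$n_detected <- n_det
      df$log2_ratio <- s$log2_ratio
      df$variance <- s$variance
      df$uniqueness <- uniq_side
      df$truth_status <- st
      df$truth_log2 <- tr
      df
    }
    main <- build_rows(acc, status, truth)
    if (config$n_isoform_groups > 0) {
      gi <- which(status != "unique")[seq_len(config$n_isoform_groups)]
      iso <- list()
      for (g in gi) for (j in 2:config$isoforms_per_group) {
        iso[[length(iso) + 1L]] <-
          build_rows(sprintf("%s-%d", acc[g], j), status[g], truth[g])
      }
      main <- rbind(main, do.call(rbind, iso))
    }
    rownames(main) <- NULL
    main
  })
}
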