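# Post-acquisition label-free differential workflow: isoform collapse,
# replicate/fold-change/significance filters, volcano table, ranked list.

#' Exact log2 threshold of the 30%-change rule
#'
#' A 30% abundance change corresponds to `|log2(1.30)| = 0.3785...`,
#' conventionally displayed as 0.38. The exact value is used internally with
#' an inclusive comparison.
#' @return Numeric scalar.
#' @export
fc_threshold_log2 <- function() abs(log2(1.30))

root_accession <- function(acc) sub("-[0-9]+$", "", acc)

#' Collapse protein isoforms to root accessions
#'
#' Rows whose accession differs only by a `-n` isoform suffix are reduced to
#' a single row per root accession: `log2_ratio` and `variance` become the
#' medians across isoforms (even counts average the middle pair),
#' `n_detected` the maximum. Tables without isoform suffixes are returned
#' unchanged; the operation is idempotent.
#'
#' @param table Data.frame with `accession`, `log2_ratio`, `variance`,
#'   `n_detected` (other columns are taken from the first isoform row).
#' @return Collapsed data.frame.
#' @export
collapse_isoforms <- function(table) {
  stopifnot(all(c("accession", "log2_ratio", "variance", "n_detected") %in%
                  names(table)))
  root <- root_accession(table$accession)
  if (!anyDuplicated(root)) {
    out <- table
    out$accession <- root
    return(out)
  }
  idx <- split(seq_len(nrow(table)), factor(root, levels = unique(root)))
  rows <- lapply(idx, function(i) {
    out <- table[i[1], , drop = FALSE]
    out$accession <- root[i[1]]
    out$log2_ratio <- stats::median(table$log2_ratio[i], na.rm = TRUE)
    out$variance <- stats::median(table$variance[i], na.rm = TRUE)
    out$n_detected <- max(table$n_detected[i])
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summary-statistic p-value for a protein ratio
#'
#' Two-sided one-sample t test of the log2 ratio against 0, computed from
#' summary statistics: `t = log2_ratio / sqrt(variance / n)` on `n - 1`
#' degrees of freedom. Zero variance reports p = 0 when the ratio is nonzero
#' and p = 1 when it is zero (flagged by attribute). Vectorized.
#'
#' @param log2_ratio Summary log2 ratio(s).
#' @param variance Replicate variance(s) (>= 0).
#' @param n Sample size(s) (>= 2).
#' @return p-value vector.
#' @export
summary_pvalue <- function(log2_ratio, variance, n) {
  if (any(n < 2, na.rm = TRUE)) stop("n must be >= 2")
  if (any(variance < 0, na.rm = TRUE)) stop("variance must be non-negative")
  len <- max(length(log2_ratio), length(variance), length(n))
  log2_ratio <- rep_len(log2_ratio, len)
  variance <- rep_len(variance, len)
  n <- rep_len(n, len)
  p <- rep(NA_real_, len)
  zero_var <- !is.na(variance) & variance == 0
  p[zero_var] <- ifelse(log2_ratio[zero_var] == 0, 1, 0)
  ok <- !is.na(variance) & variance > 0 & !is.na(log2_ratio)
  t_stat <- log2_ratio[ok] / sqrt(variance[ok] / n[ok])
  p[ok] <- 2 * stats::pt(-abs(t_stat), df = n[ok] - 1)
  attr(p, "zero_variance") <- zero_var
  p
}

#' Differential filters: replicate detection, fold change, significance
#'
#' Retains proteins detected in at least `min_detected` replicates AND with
#' `|log2_ratio| >= fc_log2` (inclusive) AND summary p <= alpha. Proteins
#' unique to one condition carry no ratio; they bypass the ratio and p
#' filters but must satisfy the detection rule in their detected condition.
#' Stage counts are recorded and monotone non-increasing.
#'
#' @param table Collapsed quantification table (see [collapse_isoforms()])
#'   with `accession`, `log2_ratio`, `variance`, `n_detected` and optionally
#'   `uniqueness`.
#' @param min_detected Minimum detected replicates (default 2 of 3).
#' @param fc_log2 Absolute log2 fold-change threshold (default the exact
#'   30%-change value, [fc_threshold_log2()]).
#' @param alpha Significance level for the summary p-value.
#' @return List of class `mm_difftable`: `table` (retained rows with `p`),
#'   `counts` (named stage counts), `thresholds`.
#' @export
filter_differential <- function(table, min_detected = 2L,
                                fc_log2 = fc_threshold_log2(), alpha = 0.05) {
  if (fc_log2 < 0) stop("fc_log2 must be non-negative")
  if (!"uniqueness" %in% names(table)) table$uniqueness <- "none"
  is_unique <- table$uniqueness != "none"
  n_input <- nrow(table)
  keep1 <- table$n_detected >= min_detected
  t1 <- table[keep1, , drop = FALSE]
  uniq1 <- t1$uniqueness != "none"
  keep2 <- uniq1 | (!is.na(t1$log2_ratio) & abs(t1$log2_ratio) >= fc_log2)
  t2 <- t1[keep2, , drop = FALSE]
  uniq2 <- t2$uniqueness != "none"
  p <- rep(NA_real_, nrow(t2))
  measurable <- !uniq2 & !is.na(t2$variance) & t2$n_detected >= 2
  p[measurable] <- summary_pvalue(t2$log2_ratio[measurable],
                                  t2$variance[measurable],
                                  t2$n_detected[measurable])
  keep3 <- uniq2 | (!is.na(p) & p <= alpha)
  t3 <- t2[keep3, , drop = FALSE]
  t3$p <- p[keep3]
  counts <- c(n_input = n_input,
              n_after_replicate_filter = nrow(t1),
              n_after_fc_filter = nrow(t2),
              n_after_p_filter = nrow(t3),
              n_unique_included = sum(t3$uniqueness != "none"))
  structure(list(table = t3, counts = counts,
                 thresholds = list(min_detected = min_detected,
                                   fc_log2 = fc_log2, alpha = alpha)),
            class = "mm_difftable")
}

#' @export
print.mm_difftable <- function(x, ...) {
  cat("<mm_difftable>\n")
  print(x$counts)
  cat(sprintf("thresholds: >=%d replicates, |log2 ratio| >= %.4f, p <= %g\n",
              x$thresholds$min_detected, x$thresholds$fc_log2,
              x$thresholds$alpha))
  invisible(x)
}

#' Volcano-plot table
#'
#' One row per quantified (non-unique) protein: log2 ratio, -log10 p, and a
#' status (`up` / `down` / `ns`) assigned with the same inclusive thresholds
#' as [filter_differential()].
#'
#' @inheritParams filter_differential
#' @return Data.frame: `accession`, `log2_ratio`, `neg_log10_p`, `status`.
#' @export
volcano_table <- function(table, min_detected = 2L,
                          fc_log2 = fc_threshold_log2(), alpha = 0.05) {
  if (!"uniqueness" %in% names(table)) table$uniqueness <- "none"
  t0 <- table[table$uniqueness == "none" & !is.na(table$log2_ratio) &
                table$n_detected >= 2, , drop = FALSE]
  p <- as.numeric(summary_pvalue(t0$log2_ratio, t0$variance, t0$n_detected))
  sig <- t0$n_detected >= min_detected & abs(t0$log2_ratio) >= fc_log2 &
    !is.na(p) & p <= alpha
  data.frame(accession = t0$accession, log2_ratio = t0$log2_ratio,
             neg_log10_p = -log10(p),
             status = ifelse(!sig, "ns",
                             ifelse(t0$log2_ratio > 0, "up", "down")))
}

#' Metric-ranked gene list for pre-ranked enrichment
#'
#' Excludes proteins unique to one condition (no finite ratio), sorts by the
#' log2(P/C) ratio in descending order with a deterministic tie-break by
#' accession.
#'
#' @param table Collapsed quantification table.
#' @return Data.frame `(id, metric)` sorted by metric descending.
#' @export
ranked_list <- function(table) {
  if (!"uniqueness" %in% names(table)) table$uniqueness <- "none"
  t0 <- table[table$uniqueness == "none" & !is.na(table$log2_ratio), , drop = FALSE]
  if (!nrow(t0)) stop("no ranked entries: table is empty after exclusions")
  ord <- order(-t0$log2_ratio, t0$accession)
  out <- data.frame(id = t0$accession[ord], metric = t0$log2_ratio[ord])
  rownames(out) <- NULL
  out
}
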