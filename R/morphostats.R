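# Distributional statistics for the morphology pipeline: kernel densities,
# per-sample Kolmogorov-Smirnov distances to a pooled reference, balanced
# two-way ANOVA, and the Wilcoxon rank-sum test.

#' Gaussian kernel density estimate of a morphological parameter
#'
#' Silverman-type bandwidth `0.9 * min(sd, IQR/1.34) * n^(-1/5)` (the
#' `bw.nrd0` rule) on a 512-point grid spanning the data +/- 3 bandwidths,
#' optionally after a log transform. The returned density is renormalized so
#' its trapezoidal integral is exactly 1.
#'
#' @param values Numeric sample (>= 2 distinct values).
#' @param transform `"identity"` or `"log"` (natural log; requires positive
#'   values).
#' @param parameter Optional parameter name carried in the result.
#' @return List of class `density_estimate`: `x`, `y`, `bw`, `transform`,
#'   `parameter`, `n`.
#' @export
density_estimate <- function(values, transform = c("identity", "log"),
                             parameter = NA_character_) {
  transform <- match.arg(transform)
  values <- values[is.finite(values)]
  if (transform == "log") {
    if (any(values <= 0)) stop("log transform requires positive values")
    values <- log(values)
  }
  if (length(values) < 2L || length(unique(values)) < 2L)
    stop("density_estimate needs at least 2 distinct values")
  d <- stats::density(values, bw = "nrd0", n = 512L, cut = 3)
  area <- sum(diff(d$x) * (utils::head(d$y, -1) + utils::tail(d$y, -1)) / 2)
  structure(list(x = d$x, y = d$y / area, bw = d$bw, transform = transform,
                 parameter = parameter, n = length(values)),
            class = "density_estimate")
}

#' Two-sample Kolmogorov-Smirnov distance
#'
#' The supremum over x of the absolute difference between the two empirical
#' cumulative distribution functions, computed on the raw values (invariant
#' under strictly increasing transforms of both samples). The optional
#' p-value is the asymptotic two-sample KS p.
#'
#' @param sample,reference Non-empty numeric vectors.
#' @param p_value Also compute the asymptotic p-value?
#' @return `D` (numeric in `[0, 1]`), or a list `(D, p)` when
#'   `p_value = TRUE`.
#' @export
ks_distance <- function(sample, reference, p_value = FALSE) {
  x <- sample[is.finite(sample)]; y <- reference[is.finite(reference)]
  if (!length(x) || !length(y)) stop("ks_distance requires non-empty samples")
  n <- length(x); m <- length(y)
  all_v <- c(x, y)
  ord <- order(all_v)
  z <- cumsum(ifelse(ord <= n, 1 / n, -1 / m))
  # at ties, only the value after processing all tied observations counts
  v_sorted <- all_v[ord]
  last_of_run <- c(v_sorted[-1] != v_sorted[-length(v_sorted)], TRUE)
  d <- max(abs(z[last_of_run]))
  if (!p_value) return(d)
  en <- sqrt(n * m / (n + m))
  t_stat <- (en + 0.12 + 0.11 / en) * d
  p <- 2 * sum((-1)^(seq_len(100) - 1) * exp(-2 * t_stat^2 * seq_len(100)^2))
  list(D = d, p = min(1, max(0, p)))
}

#' Per-sample KS distances to the pooled reference distribution
#'
#' The reference pool is every particle value from the reference study cell
#' (by default control subjects under vehicle treatment). Each sample unit
#' (field of view, or subject with fields pooled) gets the KS distance of its
#' own particle values to that pool. When a unit belongs to the pool itself
#' and `leave_one_out = TRUE` (default), its particles are removed from the
#' reference for its own comparison, avoiding self-comparison bias.
#'
#' @param particles Particle data.frame (from [measure_particles()]) with
#'   `subject`, `group`, `treatment`, `fov` columns.
#' @param parameter Morphological parameter column name.
#' @param unit `"fov"` (default; densities are per field of view) or
#'   `"subject"`.
#' @param leave_one_out Exclude a pool unit's own particles from its
#'   reference?
#' @param ref_group,ref_treatment The study cell defining the reference pool.
#' @return Data.frame of class `ks_distance_table`: one row per unit with
#'   `D`, `p`, `n_sample`, `n_reference` and the unit's metadata.
#' @export
sample_distance_table <- function(particles, parameter, unit = c("fov", "subject"),
                                  leave_one_out = TRUE,
                                  ref_group = "CTRL", ref_treatment = "DMSO") {
  unit <- match.arg(unit)
  if (!parameter %in% names(particles))
    stop("unknown parameter: ", parameter)
  needed <- c("subject", "group", "treatment", "fov")
  if (!all(needed %in% names(particles)))
    stop("particles must carry columns: ", paste(needed, collapse = ", "))
  particles$.unit <- if (unit == "fov")
    interaction(particles$subject, particles$treatment, particles$fov, drop = TRUE)
  else interaction(particles$subject, particles$treatment, drop = TRUE)
  in_ref <- particles$group == ref_group & particles$treatment == ref_treatment
  if (!any(in_ref))
    stop("empty reference pool: no particles in ", ref_group, "/", ref_treatment)
  ref_all <- particles[[parameter]][in_ref]
  units <- unique(particles$.unit)
  rows <- lapply(units, function(u) {
    sel <- particles$.unit == u
    vals <- particles[[parameter]][sel]
    ref <- if (leave_one_out && any(sel & in_ref))
      particles[[parameter]][in_ref & !sel] else ref_all
    if (!length(ref)) stop("reference pool empty after leave-one-out")
    ks <- ks_distance(vals, ref, p_value = TRUE)
    data.frame(sample_id = as.character(u),
               subject = particles$subject[sel][1],
               group = particles$group[sel][1],
               treatment = particles$treatment[sel][1],
               fov = if (unit == "fov") particles$fov[sel][1] else NA,
               parameter = parameter,
               D = ks$D, p = ks$p,
               n_sample = length(vals), n_reference = length(ref))
  })
  out <- do.call(rbind, rows)
  attr(out, "reference") <- sprintf("%s/%s pooled particles%s", ref_group,
                                    ref_treatment,
                                    if (leave_one_out) " (leave-one-out)" else "")
  class(out) <- c("ks_distance_table", "data.frame")
  out
}

#' Balanced two-way fixed-effects ANOVA with interaction
#'
#' Closed-form sums of squares for a balanced two-factor design:
#' factor A (e.g. mutation), factor B (e.g. treatment), their interaction and
#' the residual. F statistics are mean squares over the residual mean square,
#' p-values from the F distribution. A completely degenerate response (all
#' equal) reports zero sums of squares and `NaN` F with `degenerate = TRUE`.
#' Unbalanced designs or empty cells are an error naming the offending cell.
#'
#' @param response Numeric response vector.
#' @param a,b Factors (coerced) of equal length with `response`.
#' @param names_ab Labels for the two factors in the output table.
#' @return Object of class `mm_anova` with a `table` data.frame
#'   (term, SS, df, MS, F, p) and a `balanced` flag.
#' @export
two_way_anova <- function(response, a, b, names_ab = c("A", "B")) {
  a <- factor(a); b <- factor(b)
  stopifnot(length(response) == length(a), length(a) == length(b))
  if (nlevels(a) < 2L || nlevels(b) < 2L)
    stop("both factors need at least 2 levels")
  counts <- table(a, b)
  if (any(counts == 0)) {
    bad <- which(counts == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: %s=%s, %s=%s", names_ab[1],
                 levels(a)[bad[1]], names_ab[2], levels(b)[bad[2]]))
  }
  if (length(unique(as.vector(counts))) != 1L)
    stop("unbalanced design: closed-form two-way ANOVA requires equal cell counts")
  n <- as.vector(counts)[1]
  I <- nlevels(a); J <- nlevels(b); N <- length(response)
  g <- mean(response)
  am <- tapply(response, a, mean)
  bm <- tapply(response, b, mean)
  cm <- tapply(response, list(a, b), mean)
  ss_a <- J * n * sum((am - g)^2)
  ss_b <- I * n * sum((bm - g)^2)
  ss_int <- n * sum((cm - outer(am, rep(1, J)) - outer(rep(1, I), bm) + g)^2)
  fitted_cell <- cm[cbind(a, b)]
  ss_err <- sum((response - fitted_cell)^2)
  ss_tot <- sum((response - g)^2)
  df <- c(I - 1, J - 1, (I - 1) * (J - 1), N - I * J)
  ss <- c(ss_a, ss_b, ss_int, ss_err)
  ms <- ss / ifelse(df > 0, df, NA)
  degenerate <- ss_tot < .Machine$double.eps * max(1, sum(response^2))
  f <- if (df[4] > 0 && ms[4] > 0 && !degenerate) ms[1:3] / ms[4] else rep(NaN, 3)
  p <- ifelse(is.nan(f), NaN, stats::pf(f, df[1:3], df[4], lower.tail = FALSE))
  tab <- data.frame(term = c(names_ab[1], names_ab[2],
                             paste(names_ab, collapse = ":"), "Residuals"),
                    SS = ss, df = df, MS = ms, F = c(f, NA), p = c(p, NA))
  structure(list(table = tab, balanced = TRUE, degenerate = degenerate,
                 SS_total = ss_tot, n_per_cell = n),
            class = "mm_anova")
}

#' @export
print.mm_anova <- function(x, ...) {
  cat("Balanced two-way ANOVA", if (x$degenerate) "(degenerate response)", "\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Wilcoxon rank-sum test
#'
#' Mann-Whitney U with midranks for ties. The two-sided p-value is exact (by
#' enumeration of all rank assignments) when `n + m <= 12` and there are no
#' ties; otherwise a normal approximation with continuity and tie correction
#' is used.
#'
#' @param x,y Non-empty numeric vectors.
#' @return List: `U` (statistic for `x`), `p` (two-sided), `method`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n <- length(x); m <- length(y)
  all_v <- c(x, y)
  r <- rank(all_v)
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  has_ties <- anyDuplicated(all_v) > 0
  if (n + m <= 12 && !has_ties) {
    combs <- utils::combn(n + m, n)
    sums <- colSums(matrix(seq_len(n + m)[combs], nrow = n))
    w_obs <- sum(r[seq_len(n)])
    p_le <- mean(sums <= w_obs)
    p_ge <- mean(sums >= w_obs)
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(U = u, p = p, method = "exact"))
  }
  mu <- n * m / 2
  tie_tab <- table(all_v)
  tie_corr <- sum(tie_tab^3 - tie_tab) / ((n + m) * (n + m - 1))
  sigma <- sqrt(n * m / 12 * (n + m + 1 - tie_corr))
  if (sigma == 0) return(list(U = u, p = 1, method = "normal"))
  z <- (u - mu - sign(u - mu) * 0.5) / sigma
  list(U = u, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}
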