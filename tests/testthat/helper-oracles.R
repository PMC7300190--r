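# Independent oracles and fixture builders used across the suite.

# Naive Huang scan: recompute the fuzziness criterion for every candidate
# level with plain loops, independent of the package's cumulative-sum path.
# Returns every minimizing level (the package picks the plateau middle).
oracle_huang <- function(counts) {
  lev <- 0:255
  nz <- which(counts > 0) - 1L
  first <- min(nz); last <- max(nz)
  C <- last - first
  cand <- first:(last - 1L)
  ent <- sapply(cand, function(t) {
    below <- lev <= t
    mu0 <- sum(counts[below] * lev[below]) / sum(counts[below])
    mu1 <- sum(counts[!below] * lev[!below]) / sum(counts[!below])
    e <- 0
    for (g in lev[counts > 0]) {
      mu <- if (g <= t) mu0 else mu1
      u <- 1 / (1 + abs(g - mu) / C)
      s <- 0
      if (u > 0 && u < 1) s <- -(u * log(u) + (1 - u) * log(1 - u))
      e <- e + counts[g + 1L] * s
    }
    e
  })
  cand[ent <= min(ent) + 1e-12 * max(1, abs(min(ent)))]
}

# All integer fixed points of the intermeans map (exhaustive scan).
oracle_isodata_fixed_points <- function(counts) {
  lev <- 0:255
  nz <- which(counts > 0) - 1L
  out <- integer(0)
  for (t in min(nz):(max(nz) - 1L)) {
    below <- lev <= t
    w0 <- sum(counts[below]); w1 <- sum(counts[!below])
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[below] * lev[below]) / w0
    mu1 <- sum(counts[!below] * lev[!below]) / w1
    if (as.integer(round((mu0 + mu1) / 2)) == t) out <- c(out, t)
  }
  out
}

# Brute-force two-sample KS: evaluate both ECDFs at every observed value.
oracle_ks <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  d <- 0
  for (v in pts) d <- max(d, abs(mean(x <= v) - mean(y <= v)))
  d
}

# Convex-polygon area by triangle-fan decomposition (cross products),
# a different route than the shoelace used in the package.
oracle_hull_area <- function(rows, cols) {
  x <- c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5)
  y <- c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5)
  h <- grDevices::chull(x, y)
  xs <- x[h]; ys <- y[h]
  a <- 0
  for (i in 2:(length(h) - 1L)) {
    a <- a + abs((xs[i] - xs[1]) * (ys[i + 1] - ys[1]) -
                   (xs[i + 1] - xs[1]) * (ys[i] - ys[1])) / 2
  }
  a
}

rasterize_disk <- function(radius_px, pad = 10L) {
  n <- 2L * (radius_px + pad)
  ctr <- n / 2
  xx <- matrix(rep(seq_len(n), n), n); yy <- t(xx)
  (xx - ctr)^2 + (yy - ctr)^2 <= radius_px^2
}

# rectangle with long side w along the image x-axis (columns), rotated
# `angle_deg` counter-clockwise with y pointing up (the package convention)
rasterize_rect <- function(w, h, angle_deg = 0, pad = 10L) {
  n <- 2L * pad + as.integer(ceiling(sqrt(w^2 + h^2)))
  ctr <- n / 2
  rowm <- matrix(rep(seq_len(n), n), n)      # varies along rows
  colm <- t(rowm)                            # varies along columns
  x <- colm - ctr; y <- -(rowm - ctr)
  th <- angle_deg * pi / 180
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  abs(u) <= w / 2 & abs(v) <= h / 2
}

# small particle table with explicit study metadata
toy_particles <- function() {
  set.seed(99)
  grid <- expand.grid(subject = c("C1", "C2", "P1", "P2"),
                      treatment = c("DMSO", "CCCP"), fov = 1:3,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    data.frame(subject = g$subject,
               group = if (startsWith(g$subject, "C")) "CTRL" else "MUT",
               treatment = g$treatment, fov = g$fov,
               circularity = stats::rbeta(40, 3, 3))
  })
  do.call(rbind, rows)
}
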