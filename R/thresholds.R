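#' 256-bin gray-level histogram of an image
#'
#' Real-valued images are binned to 256 gray levels by min-max scaling
#' (level `g = floor(255 * (x - min) / (max - min))`); images that are already
#' integer-valued in `[0, 255]` keep their native levels. The returned mapping
#' converts a gray level back to the intensity at the upper edge of its bin,
#' which is the scale on which thresholds are applied
#' (foreground = intensity strictly greater than the mapped threshold).
#'
#' @param img A `calibrated_image` or numeric matrix/array.
#' @return A list with `counts` (length 256, levels 0..255), `level_to_intensity`
#'   (function), and `binned` (integer array of gray levels, same shape).
#' @export
gray_histogram <- function(img) {
  px <- if (inherits(img, "calibrated_image")) img$pixels else img
  if (!all(is.finite(px))) stop("image contains non-finite values")
  lo <- min(px); hi <- max(px)
  native <- all(px == floor(px)) && lo >= 0 && hi <= 255
  if (native) {
    g <- array(as.integer(px), dim = dim(px))
    map <- function(t) t + 0  # identity on the native integer scale
  } else {
    if (hi == lo) {
      g <- array(0L, dim = dim(px))
    } else {
      g <- array(pmin(255L, as.integer(floor(255 * (px - lo) / (hi - lo)))),
                 dim = dim(px))
    }
    map <- function(t) lo + (t + 0.5) / 255 * (hi - lo)
  }
  counts <- tabulate(as.vector(g) + 1L, nbins = 256L)
  list(counts = counts, level_to_intensity = map, binned = g)
}

check_histogram <- function(counts) {
  if (length(counts) != 256L || any(counts < 0))
    stop("histogram must be 256 non-negative gray-level counts")
  if (sum(counts > 0) < 2L)
    stop("degenerate histogram: fewer than 2 nonempty gray levels")
  invisible(counts)
}

#' Huang fuzzy-entropy automatic threshold
#'
#' Scans all candidate gray levels and returns the one minimizing the
#' Huang-Wang measure of fuzziness. For a candidate `t`, pixels at levels
#' `<= t` belong to the background class with mean `mu0(t)` and pixels `> t`
#' to the foreground class with mean `mu1(t)`; the membership of level `g` is
#' `u(g) = 1 / (1 + |g - mu_class(g)| / C)` with `C` the gray-level range of
#' the histogram, and the fuzziness is the Shannon entropy
#' `-sum_g h(g) * (u log u + (1-u) log(1-u))`. When several candidates tie at
#' the minimum (e.g. fully separated spike histograms, where the fuzziness is
#' zero on a plateau), the middle of the tied plateau is returned. Foreground
#' is strictly greater than the returned threshold.
#'
#' @param counts 256-bin gray-level histogram (levels 0..255).
#' @return Integer threshold gray level.
#' @export
huang_threshold <- function(counts) {
  check_histogram(counts)
  lev <- 0:255
  nz <- which(counts > 0)
  first <- nz[1L] - 1L; last <- nz[length(nz)] - 1L
  C <- last - first
  cw <- cumsum(counts)                 # weight below or at t
  cwl <- cumsum(counts * lev)          # weighted level sum below or at t
  total_w <- cw[256L]; total_wl <- cwl[256L]
  cand <- first:(last - 1L)
  ent <- vapply(cand, function(t) {
    w0 <- cw[t + 1L]; w1 <- total_w - w0
    mu0 <- cwl[t + 1L] / w0
    mu1 <- (total_wl - cwl[t + 1L]) / w1
    mu <- ifelse(lev <= t, mu0, mu1)
    u <- 1 / (1 + abs(lev - mu) / C)
    s <- -(u * log(u) + (1 - u) * log1p(-u))
    s[!is.finite(s)] <- 0
    sum(counts * s)
  }, numeric(1))
  tied <- which(ent <= min(ent) + 1e-12 * max(1, abs(min(ent))))
  cand[tied[ceiling(length(tied) / 2)]]
}

#' IsoData (iterative intermeans) automatic threshold
#'
#' Starting from the rounded global mean gray level, iterates
#' `T <- round((mean below-or-at T + mean above T) / 2)` until a fixed point
#' (or a cycle, in which case the current value is returned). Foreground is
#' strictly greater than the returned threshold.
#'
#' @param counts 256-bin gray-level histogram (levels 0..255).
#' @return Integer threshold gray level.
#' @export
isodata_threshold <- function(counts) {
  check_histogram(counts)
  lev <- 0:255
  nz <- which(counts > 0)
  last <- nz[length(nz)] - 1L
  t_cur <- as.integer(round(sum(counts * lev) / sum(counts)))
  t_cur <- min(t_cur, last - 1L)
  seen <- integer(0)
  repeat {
    below <- lev <= t_cur
    w0 <- sum(counts[below]); w1 <- sum(counts[!below])
    if (w1 == 0) { t_cur <- t_cur - 1L; next }
    if (w0 == 0) { t_cur <- t_cur + 1L; next }
    mu0 <- sum(counts[below] * lev[below]) / w0
    mu1 <- sum(counts[!below] * lev[!below]) / w1
    t_new <- as.integer(round((mu0 + mu1) / 2))
    t_new <- min(max(t_new, 0L), last - 1L)
    if (t_new == t_cur) return(t_cur)
    if (t_new %in% seen) return(t_new)
    seen <- c(seen, t_cur)
    t_cur <- t_new
  }
}

#' Apply an automatic histogram threshold to an image
#'
#' Bins the image to 256 gray levels (see [gray_histogram()]), computes the
#' requested automatic threshold, and returns the binary foreground
#' (strictly greater than the threshold) together with the threshold on both
#' scales.
#'
#' @param img A `calibrated_image` or numeric matrix/array.
#' @param method `"huang"` or `"isodata"`.
#' @return List: `mask` (logical array, same shape), `threshold_level`
#'   (0..255), `threshold_intensity` (original intensity scale), `method`.
#' @export
auto_threshold <- function(img, method = c("huang", "isodata")) {
  method <- match.arg(method)
  h <- gray_histogram(img)
  t_lev <- switch(method,
                  huang = huang_threshold(h$counts),
                  isodata = isodata_threshold(h$counts))
  list(mask = h$binned > t_lev,
       threshold_level = t_lev,
       threshold_intensity = h$level_to_intensity(t_lev),
       method = method)
}
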