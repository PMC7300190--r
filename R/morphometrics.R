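# Moore-neighbor boundary tracing and per-particle shape descriptors.
#
# Perimeter convention: closed 8-connected boundary walk through boundary
# pixel centers, straight steps counting 1 and diagonal steps sqrt(2), with
# no corner-smoothing correction. An isolated pixel (no walk possible) takes
# the unit-square perimeter 4. Interior holes do not contribute.

# Moore tracing on a logical matrix containing a single 8-connected object.
# Returns the ordered (row, col) outer-boundary pixel sequence; the chain is
# closed implicitly (last element connects back to the first). Stops when the
# start pixel is re-entered with the same continuation (Jacob's criterion).
moore_trace <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  start <- which(m)[1L]           # column-major: leftmost column, topmost row
  sr <- ((start - 1L) %% nr) + 1L
  sc <- ((start - 1L) %/% nr) + 1L
  # clockwise order starting at W: W, NW, N, NE, E, SE, S, SW
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  fg <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && m[r, c]
  path_r <- sr; path_c <- sc
  pr <- sr; pc <- sc
  br <- sr; bc <- sc - 1L         # backtrack: W neighbor is background here
  second <- NULL
  max_steps <- 4L * sum(m) + 8L
  repeat {
    bi <- which(dr == (br - pr) & dc == (bc - pc))
    nxt <- NULL
    for (s in 1:8) {
      k <- ((bi - 1L + s) %% 8L) + 1L       # scan clockwise after backtrack
      rr <- pr + dr[k]; cc <- pc + dc[k]
      if (fg(rr, cc)) {
        kprev <- ((bi - 1L + s - 1L) %% 8L) + 1L
        nbr <- pr + dr[kprev]; nbc <- pc + dc[kprev]
        nxt <- c(rr, cc)
        break
      }
    }
    if (is.null(nxt)) return(cbind(r = sr, c = sc))   # isolated pixel
    if (is.null(second)) {
      second <- nxt
    } else if (pr == sr && pc == sc &&
               nxt[1] == second[1] && nxt[2] == second[2]) {
      break
    }
    path_r <- c(path_r, nxt[1]); path_c <- c(path_c, nxt[2])
    pr <- nxt[1]; pc <- nxt[2]; br <- nbr; bc <- nbc
    if (length(path_r) > max_steps) break   # safety net, should not trigger
  }
  n <- length(path_r)
  if (n > 1L && path_r[n] == sr && path_c[n] == sc) {
    path_r <- path_r[-n]; path_c <- path_c[-n]
  }
  cbind(r = path_r, c = path_c)
}

chain_length <- function(path) {
  n <- nrow(path)
  if (n < 2L) return(0)
  d <- path[c(2:n, 1L), , drop = FALSE] - path
  sum(sqrt(d[, 1]^2 + d[, 2]^2))
}

# Perimeter (in pixels) of a single object given its pixel coordinates.
object_perimeter_px <- function(rows, cols) {
  r0 <- min(rows); c0 <- min(cols)
  m <- matrix(FALSE, max(rows) - r0 + 2L, max(cols) - c0 + 2L)
  m[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- TRUE
  p <- chain_length(moore_trace(m))
  if (p == 0) 4 else p
}

#' Moment-based ellipse fit of a pixel set
#'
#' Fits an ellipse from the central second moments of the pixel coordinates
#' (with the 1/12 per-pixel square correction), rescaled so the ellipse area
#' equals the pixel area. The angle is that of the major axis against the
#' image x-axis, counter-clockwise with y pointing up, in `[0, 180)` degrees.
#'
#' @param rows,cols Integer pixel coordinates (image rows and columns).
#' @param calibration Pixel size in micrometres per pixel.
#' @return List with `major`, `minor` (full axis lengths, micrometres) and
#'   `angle` (degrees).
#' @export
fit_ellipse <- function(rows, cols, calibration = 1) {
  n <- length(rows)
  if (n < 1L) stop("empty pixel set")
  x <- cols; y <- -rows        # y up so angles are counter-clockwise
  mx <- mean(x); my <- mean(y)
  # population central moments + 1/12 square-pixel correction
  cxx <- sum((x - mx)^2) / n + 1 / 12
  cyy <- sum((y - my)^2) / n + 1 / 12
  cxy <- sum((x - mx) * (y - my)) / n
  tr <- cxx + cyy
  det_ <- cxx * cyy - cxy^2
  disc <- sqrt(max(0, (tr / 2)^2 - det_))
  l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 1e-12)
  a0 <- 2 * sqrt(l1); b0 <- 2 * sqrt(l2)      # semi-axes before area rescale
  s <- sqrt(n / (pi * a0 * b0))
  ang <- if (abs(cxy) < 1e-12 && cxx >= cyy) 0 else
    atan2(l1 - cxx, cxy) * 180 / pi
  ang <- ang %% 180
  list(major = 2 * s * a0 * calibration,
       minor = 2 * s * b0 * calibration,
       angle = ang)
}

hull_area_px <- function(rows, cols) {
  # convex hull over the four corners of each pixel's unit square
  x <- c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5)
  y <- c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5)
  h <- grDevices::chull(x, y)
  xs <- x[h]; ys <- y[h]
  n <- length(h)
  abs(sum(xs * ys[c(2:n, 1L)] - xs[c(2:n, 1L)] * ys)) / 2
}

#' Measure particle shape descriptors
#'
#' Per 8-connected component of a binary mask, computes the standard
#' particle-analysis descriptor set: area and perimeter (micrometre units),
#' fitted-ellipse major/minor axes and angle, aspect ratio, circularity
#' `4*pi*A/P^2`, roundness `4*A/(pi*major^2)` and solidity `A / convex hull
#' area`. Circularity, roundness and solidity are capped at 1 (digitization
#' can push the raw values slightly above). Applied slice-wise to 3D masks,
#' pooling particles across slices with a `z_slice` column.
#'
#' @param mask A `binary_mask`, or logical matrix/array with `calibration`.
#' @param calibration Pixel size (um/px) when `mask` is a bare array.
#' @param meta Optional named list of provenance columns (subject, group,
#'   treatment, fov) recycled across all particles.
#' @return A data.frame with one row per particle.
#' @export
measure_particles <- function(mask, calibration = NULL, meta = list()) {
  if (inherits(mask, "binary_mask")) {
    m <- mask$mask; cal <- mask$pixel_size_um
  } else {
    m <- mask
    if (is.null(calibration)) stop("`calibration` required for bare arrays")
    cal <- calibration
  }
  if (!is.numeric(cal) || cal <= 0) stop("calibration must be positive")
  slices <- if (length(dim(m)) == 3L) seq_len(dim(m)[3L]) else 1L
  out <- list()
  for (z in slices) {
    mz <- if (length(dim(m)) == 3L) m[, , z] else m
    if (!any(mz)) next
    lab <- label_components(mz)
    for (id in seq_len(max(lab))) {
      idx <- which(lab == id, arr.ind = TRUE)
      rows <- idx[, 1]; cols <- idx[, 2]
      n_px <- length(rows)
      area <- n_px * cal^2
      perim <- object_perimeter_px(rows, cols) * cal
      ell <- fit_ellipse(rows, cols, cal)
      circ <- min(1, 4 * pi * area / perim^2)
      rnd <- min(1, 4 * area / (pi * ell$major^2))
      sol <- min(1, n_px / hull_area_px(rows, cols))
      out[[length(out) + 1L]] <- data.frame(
        particle = id, z_slice = z, n_px = n_px,
        area = area, perimeter = perim,
        major_axis = ell$major, minor_axis = ell$minor, angle = ell$angle,
        aspect_ratio = ell$major / ell$minor,
        circularity = circ, roundness = rnd, solidity = sol)
    }
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(particle = integer(0), z_slice = integer(0), n_px = integer(0),
               area = numeric(0), perimeter = numeric(0),
               major_axis = numeric(0), minor_axis = numeric(0),
               angle = numeric(0), aspect_ratio = numeric(0),
               circularity = numeric(0), roundness = numeric(0),
               solidity = numeric(0))
  for (nm in names(meta)) df[[nm]] <- if (nrow(df)) meta[[nm]] else
    meta[[nm]][0]
  df
}

#' Names of the morphological parameters measured per particle
#' @return Character vector of descriptor column names.
#' @export
morphology_parameters <- function() {
  c("area", "perimeter", "major_axis", "minor_axis", "angle",
    "aspect_ratio", "circularity", "roundness", "solidity")
}
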