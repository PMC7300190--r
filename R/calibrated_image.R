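#' Calibrated grayscale image or z-stack
#'
#' Wraps a numeric matrix (2D) or array (3D, third dimension = z-slice) with
#' the physical pixel size and a channel label. All image operators in the
#' package consume and return this container so that calibration travels with
#' the pixel data.
#'
#' @param pixels Numeric matrix (2D image) or 3D array (z-stack, dim 3 = slice).
#' @param pixel_size_um Pixel size in micrometres per pixel (> 0).
#' @param channel Character channel label (e.g. `"mito"`, `"marker"`).
#' @param bit_depth Optional integer bit depth of the source data; when given,
#'   intensity operators clip to `[0, 2^bit_depth - 1]`.
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, pixel_size_um, channel = "gray",
                             bit_depth = NULL) {
  if (!is.numeric(pixels) || !(length(dim(pixels)) %in% c(2L, 3L)))
    stop("`pixels` must be a numeric matrix or 3D array")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  if (!is.null(bit_depth)) {
    bit_depth <- as.integer(bit_depth)
    stopifnot(bit_depth >= 1L)
  }
  structure(
    list(pixels = pixels, pixel_size_um = as.numeric(pixel_size_um),
         channel = as.character(channel), bit_depth = bit_depth),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<calibrated_image> %s, %s px, %.4g um/px%s\n",
              x$channel, paste(d, collapse = " x "), x$pixel_size_um,
              if (is.null(x$bit_depth)) "" else sprintf(", %d-bit", x$bit_depth)))
  invisible(x)
}

is_zstack <- function(img) length(dim(img$pixels)) == 3L

n_slices <- function(img) if (is_zstack(img)) dim(img$pixels)[3L] else 1L

#' Extract one z-slice as a 2D calibrated image
#' @param img A `calibrated_image`.
#' @param z Slice index (ignored for 2D input).
#' @return A 2D `calibrated_image`.
#' @export
get_slice <- function(img, z = 1L) {
  stopifnot(inherits(img, "calibrated_image"))
  px <- if (is_zstack(img)) img$pixels[, , z] else img$pixels
  calibrated_image(px, img$pixel_size_um, img$channel, img$bit_depth)
}

#' Maximum-intensity projection of a z-stack
#'
#' Per-pixel maximum across slices; calibration and channel label preserved.
#'
#' @param zstack A 3D `calibrated_image`.
#' @return A 2D `calibrated_image`.
#' @export
max_project <- function(zstack) {
  stopifnot(inherits(zstack, "calibrated_image"))
  if (!is_zstack(zstack))
    stop("max_project() requires a 3D z-stack; input is 2D")
  px <- apply(zstack$pixels, c(1L, 2L), max)
  calibrated_image(px, zstack$pixel_size_um, zstack$channel, zstack$bit_depth)
}

# Separable Gaussian blur with symmetric (reflective) boundary handling.
# Kernel truncated at ceiling(3*sigma).
gaussian_kernel1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

reflect_index <- function(n, r) {
  if (r >= n) {
    # mirror repeatedly for very small images
    base <- c(seq_len(n), rev(seq_len(n)))
    idx <- ((seq_len(n + 2L * r) - r - 1L) %% (2L * n)) + 1L
    return(base[idx])
  }
  c(rev(seq_len(r)), seq_len(n), n + 1L - seq_len(r))
}

conv_rows <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  mp <- m[reflect_index(n, r), , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * mp[(j - 1L) + seq_len(n), , drop = FALSE]
  out
}

gaussian_blur2d <- function(m, sigma) {
  k <- gaussian_kernel1d(sigma)
  t(conv_rows(t(conv_rows(m, k)), k))
}

#' Unsharp-mask sharpening filter
#'
#' Subtracts a weighted Gaussian blur and renormalizes:
#' `out = (I - weight * G_sigma(I)) / (1 - weight)`, applied slice-wise to
#' z-stacks, with symmetric boundary handling. The result is clipped below at
#' zero, and above at the bit-depth ceiling when the image declares one. With
#' `weight = 0` the input is returned unchanged.
#'
#' @param img A `calibrated_image`.
#' @param sigma_px Gaussian standard deviation in pixels (> 0).
#' @param weight Blur weight in `[0, 1)`.
#' @return A `calibrated_image` of the same shape.
#' @export
unsharp_mask <- function(img, sigma_px = 1.0, weight = 0.6) {
  stopifnot(inherits(img, "calibrated_image"))
  if (!is.finite(sigma_px) || sigma_px <= 0)
    stop("`sigma_px` must be positive")
  if (!is.finite(weight) || weight < 0 || weight >= 1)
    stop("`weight` must be in [0, 1)")
  hi <- if (is.null(img$bit_depth)) Inf else 2^img$bit_depth - 1
  sharpen <- function(m) {
    out <- (m - weight * gaussian_blur2d(m, sigma_px)) / (1 - weight)
    pmin(pmax(out, 0), hi)
  }
  px <- img$pixels
  if (is_zstack(img)) {
    for (z in seq_len(dim(px)[3L])) px[, , z] <- sharpen(px[, , z])
  } else {
    px <- sharpen(px)
  }
  calibrated_image(px, img$pixel_size_um, img$channel, img$bit_depth)
}
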