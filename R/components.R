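#' 8-connected component labeling
#'
#' Labels connected foreground regions using the 8-neighborhood (horizontal,
#' vertical and diagonal adjacency). Built on 4-connected labeling
#' (`EBImage::bwlabel`) followed by a union-find merge of labels that touch
#' diagonally, so diagonal chains form a single object.
#'
#' @param mask Logical or 0/1 numeric matrix.
#' @return Integer matrix of component labels (0 = background), labels
#'   consecutive from 1 in scan order of first occurrence.
#' @export
label_components <- function(mask) {
  m <- if (is.logical(mask)) mask else mask != 0
  if (!any(m)) return(matrix(0L, nrow(m), ncol(m)))
  lab <- EBImage::imageData(EBImage::bwlabel(m * 1))
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  nl <- max(lab)
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  nr <- nrow(lab); nc <- ncol(lab)
  # two independent diagonal directions cover all diagonal adjacencies
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # SE neighbor
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))    # NE neighbor
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (i in seq_len(nrow(pairs))) unite(pairs[i, 1], pairs[i, 2])
  }
  roots <- vapply(seq_len(nl), find, integer(1))
  # relabel consecutively in order of first appearance in column-major scan
  new_id <- integer(nl)
  uroots <- unique(roots[as.vector(lab)[as.vector(lab) > 0]])
  new_id[uroots] <- seq_along(uroots)
  out <- lab
  out[lab > 0] <- new_id[roots[lab[lab > 0]]]
  out
}

#' Binary mask with provenance
#'
#' @param mask Logical matrix (or 3D logical array for stacks).
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @param provenance Named list describing how the mask was produced
#'   (threshold method and value, cleanup parameters).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(mask, pixel_size_um, provenance = list()) {
  stopifnot(is.logical(mask), length(dim(mask)) %in% c(2L, 3L),
            pixel_size_um > 0)
  structure(list(mask = mask, pixel_size_um = as.numeric(pixel_size_um),
                 provenance = provenance),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s px, %.4g um/px, %d foreground px\n",
              paste(dim(x$mask), collapse = " x "), x$pixel_size_um,
              sum(x$mask)))
  invisible(x)
}

clean_slice <- function(m, min_area_px, clear_border) {
  if (!any(m)) return(m)
  lab <- label_components(m)
  nl <- max(lab)
  keep <- tabulate(lab[lab > 0], nbins = nl) >= min_area_px
  if (clear_border) {
    border_labs <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    keep[border_labs[border_labs > 0]] <- FALSE
  }
  out <- m
  out[lab > 0] <- keep[lab[lab > 0]]
  out
}

#' Threshold an image and remove aberrant objects
#'
#' Binarizes at `pixels > threshold`, then removes 8-connected components
#' smaller than `min_area_px` and, optionally, components touching the image
#' border. Applied slice-wise to z-stacks. The operation is idempotent on its
#' own output.
#'
#' @param img A `calibrated_image` (or numeric matrix/array with
#'   `pixel_size_um` supplied).
#' @param threshold Intensity threshold (foreground strictly greater).
#' @param min_area_px Minimum component area in pixels (>= 0).
#' @param clear_border Remove components touching the image border?
#' @param pixel_size_um Calibration, required when `img` is a bare array.
#' @return A `binary_mask` with provenance recording all parameters.
#' @export
binarize_and_clean <- function(img, threshold, min_area_px = 5L,
                               clear_border = FALSE, pixel_size_um = NULL) {
  if (inherits(img, "calibrated_image")) {
    px <- img$pixels; cal <- img$pixel_size_um
  } else {
    px <- img
    if (is.null(pixel_size_um)) stop("`pixel_size_um` required for bare arrays")
    cal <- pixel_size_um
  }
  if (min_area_px < 0) stop("`min_area_px` must be non-negative")
  m <- px > threshold
  if (length(dim(m)) == 3L) {
    for (z in seq_len(dim(m)[3L]))
      m[, , z] <- clean_slice(m[, , z], min_area_px, clear_border)
  } else {
    m <- clean_slice(m, min_area_px, clear_border)
  }
  binary_mask(m, cal,
              provenance = list(threshold = threshold,
                                min_area_px = as.integer(min_area_px),
                                clear_border = clear_border))
}

#' Segment one channel with an automatic threshold and cleanup
#'
#' Convenience wrapper: 256-level binning, automatic threshold (per slice for
#' z-stacks unless `global_threshold = TRUE`), binarization and cleanup.
#'
#' @inheritParams binarize_and_clean
#' @param method `"huang"` or `"isodata"`.
#' @param global_threshold For stacks: compute one threshold from the pooled
#'   histogram instead of per slice.
#' @return A `binary_mask`; provenance records per-slice thresholds.
#' @export
segment_image <- function(img, method = c("huang", "isodata"),
                          min_area_px = 5L, clear_border = FALSE,
                          global_threshold = FALSE) {
  stopifnot(inherits(img, "calibrated_image"))
  method <- match.arg(method)
  px <- img$pixels
  if (length(dim(px)) == 3L && !global_threshold) {
    mask <- array(FALSE, dim(px))
    thr <- numeric(dim(px)[3L])
    for (z in seq_len(dim(px)[3L])) {
      at <- auto_threshold(px[, , z], method)
      thr[z] <- at$threshold_intensity
      mask[, , z] <- clean_slice(at$mask, min_area_px, clear_border)
    }
  } else {
    at <- auto_threshold(px, method)
    thr <- at$threshold_intensity
    mask <- at$mask
    if (length(dim(mask)) == 3L) {
      for (z in seq_len(dim(mask)[3L]))
        mask[, , z] <- clean_slice(mask[, , z], min_area_px, clear_border)
    } else mask <- clean_slice(mask, min_area_px, clear_border)
  }
  binary_mask(mask, img$pixel_size_um,
              provenance = list(method = method, threshold = thr,
                                min_area_px = as.integer(min_area_px),
                                clear_border = clear_border,
                                global_threshold = global_threshold))
}
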