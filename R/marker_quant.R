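# Marker-channel quantification within the mitochondrial area, and
# whole-image fluorescence normalizations.

#' Mitochondrial area mask from a reference channel
#'
#' Maximum-projects the mitochondrial reference stack (e.g. ATP synthase
#' beta), applies the IsoData automatic threshold, and returns the binary
#' mitochondrial area with the threshold recorded in provenance.
#'
#' @param mito A `calibrated_image` (2D or z-stack).
#' @param min_area_px Optional small-object cleanup (0 disables).
#' @return A `binary_mask` (2D).
#' @export
mito_area_mask <- function(mito, min_area_px = 0L) {
  stopifnot(inherits(mito, "calibrated_image"))
  proj <- if (is_zstack(mito)) max_project(mito) else mito
  at <- auto_threshold(proj, "isodata")
  m <- at$mask
  if (min_area_px > 0) m <- clean_slice(m, min_area_px, FALSE)
  binary_mask(m, proj$pixel_size_um,
              provenance = list(method = "isodata",
                                threshold = at$threshold_intensity,
                                projection = "max",
                                min_area_px = as.integer(min_area_px)))
}

#' Marker signal per mitochondrial surface unit
#'
#' Integrated marker intensity inside the mitochondrial mask divided by the
#' mask area in square micrometres. The marker stack is max-projected to
#' match the mask's projection.
#'
#' @param marker A `calibrated_image` (2D or z-stack; projected if 3D).
#' @param mask A 2D `binary_mask` of matching shape.
#' @param meta Optional named list (sample id, group, treatment) copied into
#'   the record.
#' @return One-row data.frame: `mito_area_um2`, `marker_integrated`,
#'   `marker_per_area`, `threshold`, plus `meta` columns.
#' @export
marker_per_area <- function(marker, mask, meta = list()) {
  stopifnot(inherits(marker, "calibrated_image"), inherits(mask, "binary_mask"))
  proj <- if (is_zstack(marker)) max_project(marker) else marker
  if (!identical(dim(proj$pixels), dim(mask$mask)))
    stop("marker and mask shapes differ")
  if (!any(mask$mask)) stop("empty mitochondrial mask")
  area <- sum(mask$mask) * mask$pixel_size_um^2
  tot <- sum(proj$pixels[mask$mask])
  rec <- data.frame(mito_area_um2 = area, marker_integrated = tot,
                    marker_per_area = tot / area,
                    threshold = if (!is.null(mask$provenance$threshold))
                      mask$provenance$threshold[1] else NA_real_)
  for (nm in names(meta)) rec[[nm]] <- meta[[nm]]
  rec
}

#' Whole-image fluorescence normalized by cell count or cell area
#'
#' Integrated image intensity divided by a supplied denominator: the number
#' of cells in the field, or the total cell surface in square micrometres.
#'
#' @param img A `calibrated_image` (2D or stack; summed over all pixels).
#' @param mode `"per_cell_count"` or `"per_cell_area"` (informational).
#' @param denominator Positive cell count or cell area (um^2).
#' @return Single numeric value.
#' @export
normalized_whole_signal <- function(img, mode = c("per_cell_count", "per_cell_area"),
                                    denominator) {
  stopifnot(inherits(img, "calibrated_image"))
  mode <- match.arg(mode)
  if (!is.numeric(denominator) || length(denominator) != 1L || denominator <= 0)
    stop("`denominator` must be a single positive number")
  sum(img$pixels) / denominator
}
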