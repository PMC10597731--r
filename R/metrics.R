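# Per-slice body-composition measures: surface area (cm^2) and mean
# radiodensity (HU) for SM, VAT and SAT.

#' Tissue cross-sectional area in cm^2
#'
#' Pixel count times the physical pixel area (row spacing x column spacing in
#' mm^2), converted to cm^2. Anisotropic spacing is handled by the product,
#' never by averaging the two spacings.
#'
#' @param mask Logical matrix.
#' @param pixel_spacing_mm Length-2 positive numeric, (row, col) spacing in mm.
#' @return Area in cm^2 (0 for an empty mask).
#' @examples
#' tissue_area(matrix(TRUE, 25, 40), c(0.8, 0.8))  # 1000 px -> 6.4 cm^2
#' @export
tissue_area <- function(mask, pixel_spacing_mm) {
  if (length(pixel_spacing_mm) != 2L || any(!is.finite(pixel_spacing_mm)) ||
      any(pixel_spacing_mm <= 0))
    stop("metadata error: pixel spacings must be positive", call. = FALSE)
  sum(mask) * pixel_spacing_mm[1] * pixel_spacing_mm[2] / 100
}

#' Mean tissue radiodensity in HU
#'
#' Arithmetic mean of the unmodified HU values under the mask. An empty mask
#' yields \code{NA} (undefined), never 0: zero HU is water and would bias
#' downstream averages.
#'
#' @param hu_image Numeric HU matrix.
#' @param mask Logical matrix of the same shape.
#' @return Mean HU, or \code{NA_real_} for an empty mask.
#' @export
tissue_radiodensity <- function(hu_image, mask) {
  if (!identical(dim(hu_image), dim(mask)))
    stop("alignment error: hu_image and mask shapes differ", call. = FALSE)
  if (!any(mask)) return(NA_real_)
  mean(hu_image[mask])
}

#' Measure one slice's body composition
#'
#' Applies \code{\link{tissue_area}} and \code{\link{tissue_radiodensity}} to
#' the SM, VAT and SAT labels of a segmented slice.
#'
#' @param slice A \code{ct_slice}.
#' @param labels Integer label mask for this slice (same shape as the HU
#'   image), see \code{\link{segment_composition}}.
#' @return Data frame with columns patient_id, slice_index, is_mid, tissue,
#'   area_cm2, radiodensity_hu (one row per tissue).
#' @export
measure_slice <- function(slice, labels) {
  stopifnot(inherits(slice, "ct_slice"))
  if (!identical(dim(labels), dim(slice$hu_image)))
    stop("alignment error: label mask does not match slice", call. = FALSE)
  rows <- lapply(TISSUES, function(t) {
    m <- labels == LABEL_LEVELS[[t]]
    data.frame(patient_id = slice$patient_id,
               slice_index = slice$slice_index,
               is_mid = slice$is_mid,
               tissue = t,
               area_cm2 = tissue_area(m, slice$pixel_spacing_mm),
               radiodensity_hu = tissue_radiodensity(slice$hu_image, m),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Segment and measure every slice of a study
#'
#' @param study A \code{patient_study}.
#' @param masks Optional list of precomputed label masks (one per slice, in
#'   stack order); when NULL each slice is segmented with
#'   \code{\link{segment_composition}}.
#' @param ... Passed to \code{\link{segment_composition}}.
#' @return Data frame of per-slice measures (see \code{\link{measure_slice}}).
#' @export
measure_study <- function(study, masks = NULL, ...) {
  stopifnot(inherits(study, "patient_study"))
  if (is.null(masks))
    masks <- lapply(study$slices,
                    function(s) segment_composition(s$hu_image, ...))
  if (length(masks) != length(study$slices))
    stop("alignment error: one mask per slice required", call. = FALSE)
  do.call(rbind, Map(measure_slice, study$slices, masks))
}
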