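# Domain containers: plain lists with S3 classes and strict constructors.

#' Construct a CT slice object
#'
#' A \code{ct_slice} holds one axial CT slice already converted to Hounsfield
#' units (HU), together with the geometry metadata needed for area
#' measurement. HU values are clamped to the physically plausible range
#' [-1100, 3100].
#'
#' @param patient_id Character scalar.
#' @param hu_image Numeric 512 x 512 matrix of HU values (row = image row).
#' @param pixel_spacing_mm Numeric length-2 vector, (row spacing, column
#'   spacing) in millimetres, both positive.
#' @param slice_thickness_mm Slice thickness in millimetres, in (0, 20].
#' @param z_position_mm Longitudinal position of the slice (ImagePositionPatient
#'   z component).
#' @param slice_index 1-based position within the ordered L3 stack (NA until
#'   the slice is placed in a study).
#' @param is_mid Logical; whether this is the designated mid-L3 slice.
#' @param sop_instance_uid Optional DICOM SOP instance UID.
#' @param source_file Optional path of the file the slice was read from.
#'
#' @return An object of class \code{ct_slice}.
#' @export
new_ct_slice <- function(patient_id, hu_image, pixel_spacing_mm,
                         slice_thickness_mm, z_position_mm,
                         slice_index = NA_integer_, is_mid = FALSE,
                         sop_instance_uid = NULL, source_file = NULL) {
  if (!is.matrix(hu_image) || !is.numeric(hu_image))
    stop("hu_image must be a numeric matrix", call. = FALSE)
  if (!all(dim(hu_image) == c(512L, 512L)))
    stop("geometry error: hu_image must be exactly 512 x 512, got ",
         paste(dim(hu_image), collapse = " x "), call. = FALSE)
  if (length(pixel_spacing_mm) != 2L || any(!is.finite(pixel_spacing_mm)) ||
      any(pixel_spacing_mm <= 0))
    stop("metadata error: pixel_spacing_mm must be two positive numbers",
         call. = FALSE)
  if (!is.finite(slice_thickness_mm) || slice_thickness_mm <= 0 ||
      slice_thickness_mm > 20)
    stop("metadata error: slice_thickness_mm must lie in (0, 20]",
         call. = FALSE)
  hu_image[] <- pmin(pmax(hu_image, -1100), 3100)
  structure(
    list(patient_id = as.character(patient_id),
         hu_image = hu_image,
         pixel_spacing_mm = as.numeric(pixel_spacing_mm),
         slice_thickness_mm = as.numeric(slice_thickness_mm),
         z_position_mm = as.numeric(z_position_mm),
         slice_index = as.integer(slice_index),
         is_mid = isTRUE(is_mid),
         sop_instance_uid = sop_instance_uid,
         source_file = source_file),
    class = "ct_slice")
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf(
    "<ct_slice> patient %s  z=%.2f mm  %dx%d  spacing %.4gx%.4g mm  thickness %.3g mm%s\n",
    x$patient_id, x$z_position_mm, nrow(x$hu_image), ncol(x$hu_image),
    x$pixel_spacing_mm[1], x$pixel_spacing_mm[2], x$slice_thickness_mm,
    if (isTRUE(x$is_mid)) "  [mid-L3]" else ""))
  invisible(x)
}

#' Construct a patient study (ordered L3 slice stack)
#'
#' @param patient_id Character scalar.
#' @param sex "female" or "male" (single letters F/M are accepted).
#' @param age_years Non-negative number.
#' @param slices List of \code{ct_slice}, will be sorted by z position.
#' @param mid_index 1-based index (after z sorting) of the designated mid-L3
#'   slice. Mid-L3 designation is always an input; it is never inferred.
#'
#' @return An object of class \code{patient_study}.
#' @export
new_patient_study <- function(patient_id, sex, age_years, slices, mid_index) {
  sex <- normalize_sex(sex)
  if (!is.numeric(age_years) || age_years < 0)
    stop("age_years must be a non-negative number", call. = FALSE)
  if (length(slices) < 2L)
    stop("insufficient data: a study needs at least 2 slices ",
         "(one mid-L3 and one non-mid)", call. = FALSE)
  z <- vapply(slices, function(s) s$z_position_mm, numeric(1))
  if (anyDuplicated(z))
    stop("ordering error: duplicate z positions in study", call. = FALSE)
  ord <- order(z)
  slices <- slices[ord]
  mid_index <- as.integer(mid_index)
  if (is.na(mid_index) || mid_index < 1L || mid_index > length(slices))
    stop("designation error: mid_index out of range", call. = FALSE)
  for (i in seq_along(slices)) {
    slices[[i]]$slice_index <- i
    slices[[i]]$is_mid <- (i == mid_index)
    slices[[i]]$patient_id <- as.character(patient_id)
  }
  structure(
    list(patient_id = as.character(patient_id), sex = sex,
         age_years = as.numeric(age_years), slices = slices,
         mid_index = mid_index),
    class = "patient_study")
}

#' @export
print.patient_study <- function(x, ...) {
  cat(sprintf("<patient_study> %s  sex=%s  age=%g  %d slices (mid = %d)\n",
              x$patient_id, x$sex, x$age_years, length(x$slices), x$mid_index))
  invisible(x)
}

normalize_sex <- function(sex) {
  s <- tolower(as.character(sex))
  out <- ifelse(s %in% c("f", "female"), "female",
                ifelse(s %in% c("m", "male"), "male", NA_character_))
  if (any(is.na(out)))
    stop("sex must be 'female' or 'male' (or F/M)", call. = FALSE)
  out
}
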