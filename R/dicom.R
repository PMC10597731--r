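# Minimal DICOM Part-10 codec (explicit VR, little endian) for single-frame
# axial CT slices. Covers exactly the tag set this package reads and writes;
# sequences, compressed transfer syntaxes and multi-frame objects are out of
# scope and rejected explicitly.

UID_ROOT <- "1.2.826.0.1.3680043.10.1553."
TS_EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
SOP_CLASS_CT <- "1.2.840.10008.5.1.4.1.1.2"

TAG_NAMES <- c(
  "0008,0016" = "SOPClassUID",      "0008,0018" = "SOPInstanceUID",
  "0008,0060" = "Modality",         "0010,0010" = "PatientName",
  "0010,0020" = "PatientID",        "0010,0040" = "PatientSex",
  "0018,0050" = "SliceThickness",   "0020,0013" = "InstanceNumber",
  "0020,0032" = "ImagePositionPatient",
  "0028,0002" = "SamplesPerPixel",  "0028,0004" = "PhotometricInterpretation",
  "0028,0010" = "Rows",             "0028,0011" = "Columns",
  "0028,0030" = "PixelSpacing",     "0028,0100" = "BitsAllocated",
  "0028,0101" = "BitsStored",       "0028,0102" = "HighBit",
  "0028,0103" = "PixelRepresentation",
  "0028,1052" = "RescaleIntercept", "0028,1053" = "RescaleSlope",
  "7fe0,0010" = "PixelData")

tag_key <- function(group, elem) sprintf("%04x,%04x", group, elem)

tag_name <- function(key) {
  nm <- TAG_NAMES[[key]]
  if (is.null(nm)) key else nm
}

raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                endian = "little")
raw_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                endian = "little")

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# One explicit-VR data element as a raw vector.
dcm_element <- function(group, elem, vr, value) {
  if (is.character(value)) {
    value <- paste(value, collapse = "\\")
    bytes <- charToRaw(value)
    if (length(bytes) %% 2L == 1L)
      bytes <- c(bytes, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  } else if (is.raw(value)) {
    bytes <- value
    if (length(bytes) %% 2L == 1L) bytes <- c(bytes, as.raw(0L))
  } else if (vr == "US") {
    bytes <- raw_u16(value)
  } else if (vr == "UL") {
    bytes <- raw_u32(value)
  } else {
    stop("unsupported value type for VR ", vr, call. = FALSE)
  }
  head_ <- c(raw_u16(group), raw_u16(elem), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(head_, as.raw(c(0L, 0L)), raw_u32(length(bytes)), bytes)
  } else {
    if (length(bytes) > 65534L) stop("element too long for short VR")
    c(head_, raw_u16(length(bytes)), bytes)
  }
}

fmt_ds <- function(x) sprintf("%.10g", x)

#' Convert raw CT pixel values to Hounsfield units
#'
#' Applies the standard CT rescale transform \code{raw * slope + intercept}
#' cell by cell.
#'
#' @param raw_pixels Non-empty numeric/integer matrix of stored pixel values.
#' @param slope Rescale slope (non-zero).
#' @param intercept Rescale intercept.
#'
#' @return Numeric matrix of HU values, same shape as \code{raw_pixels}.
#' @examples
#' to_hounsfield(matrix(1024L, 2, 2), slope = 1, intercept = -1024)
#' @export
to_hounsfield <- function(raw_pixels, slope, intercept) {
  if (!is.matrix(raw_pixels) || length(raw_pixels) == 0L ||
      any(dim(raw_pixels) <= 0L))
    stop("invalid input: raw_pixels must be a non-empty matrix", call. = FALSE)
  if (!is.numeric(slope) || !is.finite(slope) || slope == 0)
    stop("invalid metadata: rescale slope must be non-zero", call. = FALSE)
  out <- raw_pixels * slope + intercept
  storage.mode(out) <- "double"
  out
}

# Deterministic SOP instance UID from patient id + instance number.
make_sop_uid <- function(patient_id, instance_number) {
  h <- sum(utf8ToInt(patient_id) * seq_along(utf8ToInt(patient_id))) %% 99999L
  sprintf("%s%d.%d", UID_ROOT, h, as.integer(instance_number))
}

#' Write one CT slice as a DICOM file
#'
#' Stores HU values as 16-bit signed integers with RescaleSlope 1 and
#' RescaleIntercept -1024 (raw = HU + 1024), in the explicit-VR little-endian
#' transfer syntax. Integer HU grids round-trip bit-exactly through
#' \code{\link{read_slice}}.
#'
#' @param slice A \code{ct_slice}.
#' @param path Output file path.
#' @param instance_number DICOM InstanceNumber (1-based position in the stack).
#' @param sex Optional patient sex stored in PatientSex ("F"/"M").
#'
#' @return \code{path}, invisibly.
#' @export
write_dicom_slice <- function(slice, path, instance_number = 1L, sex = NULL) {
  stopifnot(inherits(slice, "ct_slice"))
  intercept <- -1024
  slope <- 1
  raw_vals <- as.integer(round((slice$hu_image - intercept) / slope))
  if (any(raw_vals < -32768L | raw_vals > 32767L))
    stop("HU values out of 16-bit storage range", call. = FALSE)
  # DICOM pixel data is row-major; R matrices are column-major.
  pix <- writeBin(as.integer(t(slice$hu_image - intercept)), raw(),
                  size = 2, endian = "little")
  sop_uid <- slice$sop_instance_uid
  if (is.null(sop_uid)) sop_uid <- make_sop_uid(slice$patient_id,
                                                instance_number)
  sex_code <- if (is.null(sex)) "" else toupper(substr(sex, 1, 1))

  ds <- c(
    dcm_element(0x0008, 0x0016, "UI", SOP_CLASS_CT),
    dcm_element(0x0008, 0x0018, "UI", sop_uid),
    dcm_element(0x0008, 0x0060, "CS", "CT"),
    dcm_element(0x0010, 0x0010, "PN", slice$patient_id),
    dcm_element(0x0010, 0x0020, "LO", slice$patient_id),
    dcm_element(0x0010, 0x0040, "CS", sex_code),
    dcm_element(0x0018, 0x0050, "DS", fmt_ds(slice$slice_thickness_mm)),
    dcm_element(0x0020, 0x0013, "IS", as.character(as.integer(instance_number))),
    dcm_element(0x0020, 0x0032, "DS",
                paste(fmt_ds(c(0, 0, slice$z_position_mm)), collapse = "\\")),
    dcm_element(0x0028, 0x0002, "US", 1L),
    dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0010, "US", nrow(slice$hu_image)),
    dcm_element(0x0028, 0x0011, "US", ncol(slice$hu_image)),
    dcm_element(0x0028, 0x0030, "DS",
                paste(fmt_ds(slice$pixel_spacing_mm), collapse = "\\")),
    dcm_element(0x0028, 0x0100, "US", 16L),
    dcm_element(0x0028, 0x0101, "US", 16L),
    dcm_element(0x0028, 0x0102, "US", 15L),
    dcm_element(0x0028, 0x0103, "US", 1L),
    dcm_element(0x0028, 0x1052, "DS", fmt_ds(intercept)),
    dcm_element(0x0028, 0x1053, "DS", fmt_ds(slope)),
    dcm_element(0x7FE0, 0x0010, "OW", pix))

  meta_body <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dcm_element(0x0002, 0x0002, "UI", SOP_CLASS_CT),
    dcm_element(0x0002, 0x0003, "UI", sop_uid),
    dcm_element(0x0002, 0x0010, "UI", TS_EXPLICIT_VR_LE),
    dcm_element(0x0002, 0x0012, "UI", paste0(UID_ROOT, "1")))
  meta <- c(dcm_element(0x0002, 0x0000, "UL", length(meta_body)), meta_body)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0L), 128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
  invisible(path)
}

# Parse all data elements of an explicit-VR LE byte stream into a named list
# of list(vr=, bytes=).
parse_elements <- function(bytes, pos) {
  n <- length(bytes)
  out <- list()
  ru16 <- function(p) readBin(bytes[p + 0:1], "integer", size = 2,
                              signed = FALSE, endian = "little")
  ru32 <- function(p) readBin(bytes[p + 0:3], "integer", size = 4,
                              endian = "little")
  while (pos + 7L <= n + 1L) {
    group <- ru16(pos); elem <- ru16(pos + 2L)
    vr <- rawToChar(bytes[pos + 4:5])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("DICOM parse error: not explicit VR little endian", call. = FALSE)
    if (vr == "SQ")
      stop("unsupported DICOM element: sequences are not supported",
           call. = FALSE)
    if (vr %in% LONG_VRS) {
      len <- ru32(pos + 8L)
      start <- pos + 12L
    } else {
      len <- ru16(pos + 6L)
      start <- pos + 8L
    }
    if (len < 0L || start + len - 1L > n)
      stop("DICOM parse error: element extends past end of file",
           call. = FALSE)
    key <- tag_key(group, elem)
    out[[key]] <- list(vr = vr,
                       bytes = if (len > 0L) bytes[start:(start + len - 1L)]
                               else raw(0))
    pos <- start + len
  }
  out
}

el_string <- function(el) {
  s <- rawToChar(el$bytes[el$bytes != as.raw(0L)])
  trimws(s)
}
el_numvec <- function(el) as.numeric(strsplit(el_string(el), "\\\\")[[1]])
el_u16 <- function(el) readBin(el$bytes[1:2], "integer", size = 2,
                               signed = FALSE, endian = "little")

require_tag <- function(els, key) {
  if (is.null(els[[key]]))
    stop(sprintf("metadata error: required DICOM tag %s (%s) is missing",
                 key, tag_name(key)), call. = FALSE)
  els[[key]]
}

#' Read one axial CT slice from a DICOM file
#'
#' Parses an explicit-VR little-endian single-frame CT file, applies the
#' file's own RescaleSlope/RescaleIntercept via \code{\link{to_hounsfield}},
#' and returns a \code{\link{new_ct_slice}} object. Only 512 x 512 images are
#' accepted.
#'
#' @param path Path to a DICOM file.
#' @return A \code{ct_slice} (slice_index and is_mid are unset until the slice
#'   is placed in a study by \code{\link{load_study}}).
#' @export
read_slice <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  bytes <- readBin(path, raw(), n = file.size(path))
  if (length(bytes) < 140L || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  els <- parse_elements(bytes, 133L)
  ts <- els[["0002,0010"]]
  if (!is.null(ts) && el_string(ts) != TS_EXPLICIT_VR_LE)
    stop("unsupported transfer syntax: ", el_string(ts), call. = FALSE)
  rows <- el_u16(require_tag(els, "0028,0010"))
  cols <- el_u16(require_tag(els, "0028,0011"))
  if (rows != 512L || cols != 512L)
    stop(sprintf("geometry error: expected 512 x 512 image, got %d x %d",
                 rows, cols), call. = FALSE)
  spacing <- el_numvec(require_tag(els, "0028,0030"))
  thickness <- el_numvec(require_tag(els, "0018,0050"))[1]
  slope <- el_numvec(require_tag(els, "0028,1053"))[1]
  intercept <- el_numvec(require_tag(els, "0028,1052"))[1]
  ipp <- el_numvec(require_tag(els, "0020,0032"))
  bits <- el_u16(require_tag(els, "0028,0100"))
  if (bits != 16L)
    stop("unsupported BitsAllocated: ", bits, call. = FALSE)
  signed <- el_u16(require_tag(els, "0028,0103")) == 1L
  pix_el <- require_tag(els, "7fe0,0010")
  npix <- as.integer(rows) * as.integer(cols)
  if (length(pix_el$bytes) != 2L * npix)
    stop("pixel data length does not match Rows x Columns", call. = FALSE)
  raw_vals <- readBin(pix_el$bytes, "integer", n = npix, size = 2,
                      signed = signed, endian = "little")
  raw_mat <- matrix(raw_vals, nrow = rows, ncol = cols, byrow = TRUE)
  hu <- to_hounsfield(raw_mat, slope, intercept)
  pid_el <- els[["0010,0020"]]
  pid <- if (is.null(pid_el)) "" else el_string(pid_el)
  uid_el <- els[["0008,0018"]]
  new_ct_slice(
    patient_id = pid, hu_image = hu,
    pixel_spacing_mm = spacing, slice_thickness_mm = thickness,
    z_position_mm = ipp[3],
    sop_instance_uid = if (is.null(uid_el)) NULL else el_string(uid_el),
    source_file = normalizePath(path))
}

#' Assemble a patient study from DICOM slice files
#'
#' Reads every file, sorts slices by z position, and attaches the manually
#' designated mid-L3 slice. The mid-L3 designation is always an input; this
#' package never infers it from the images.
#'
#' @param paths Character vector (>= 2) of DICOM file paths for one patient.
#' @param mid_designation File name (or full path) identifying the mid-L3
#'   slice; must match exactly one element of \code{paths}.
#' @param sex,age_years Patient metadata.
#' @param patient_id Optional; defaults to the PatientID tag of the first file.
#'
#' @return A \code{patient_study}.
#' @export
load_study <- function(paths, mid_designation, sex, age_years,
                       patient_id = NULL) {
  if (length(paths) < 2L)
    stop("insufficient data: need at least 2 slices per study", call. = FALSE)
  hits <- which(basename(paths) == basename(mid_designation))
  if (length(hits) != 1L)
    stop(sprintf("designation error: mid slice '%s' matches %d of %d files",
                 mid_designation, length(hits), length(paths)), call. = FALSE)
  slices <- lapply(paths, read_slice)
  if (is.null(patient_id)) patient_id <- slices[[1]]$patient_id
  z <- vapply(slices, function(s) s$z_position_mm, numeric(1))
  if (anyDuplicated(z))
    stop("ordering error: duplicate z positions in study", call. = FALSE)
  mid_index <- rank(z, ties.method = "first")[hits]
  new_patient_study(patient_id, sex, age_years, slices, mid_index)
}

#' Read or write a study manifest
#'
#' The manifest is a tab-separated table with one row per DICOM file and
#' columns \code{patient_id}, \code{sex}, \code{age_years}, \code{file}
#' (relative to the manifest's directory) and \code{is_mid}.
#'
#' @param path Manifest file path.
#' @return \code{read_manifest}: a data.frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "sex", "age_years", "file", "is_mid")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("manifest is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$is_mid <- as.logical(df$is_mid)
  df
}

#' @param manifest Data.frame with the manifest columns.
#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Load every patient study listed in a manifest
#'
#' @param manifest_path Path to a manifest written by
#'   \code{\link{write_manifest}} / \code{\link{write_dicom_series}}.
#' @return Named list of \code{patient_study} objects.
#' @export
load_cohort <- function(manifest_path) {
  man <- read_manifest(manifest_path)
  base <- dirname(manifest_path)
  out <- list()
  for (pid in unique(man$patient_id)) {
    rows <- man[man$patient_id == pid, , drop = FALSE]
    if (sum(rows$is_mid) != 1L)
      stop(sprintf("designation error: patient %s has %d mid-L3 rows",
                   pid, sum(rows$is_mid)), call. = FALSE)
    out[[pid]] <- load_study(
      file.path(base, rows$file),
      mid_designation = rows$file[rows$is_mid],
      sex = rows$sex[1], age_years = rows$age_years[1], patient_id = pid)
  }
  out
}
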