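test_that("HU conversion applies the affine rescale and preserves shape", {
  expect_equal(to_hounsfield(matrix(0L, 1, 1), 1, -1024)[1, 1], -1024)
  expect_equal(to_hounsfield(matrix(1024L, 1, 1), 1, -1024)[1, 1], 0)
  expect_equal(to_hounsfield(matrix(500L, 1, 1), 2, -1000)[1, 1], 0)
  m <- matrix(1:12, 3, 4)
  out <- to_hounsfield(m, 2, -100)
  expect_identical(dim(out), dim(m))
  expect_equal(out, m * 2 - 100)
})

test_that("HU conversion is affine and exactly invertible on integers", {
  set.seed(11)
  raw <- matrix(sample.int(4096L, 100) - 1L, 10, 10)
  hu <- to_hounsfield(raw, 1, -1024)
  expect_equal((hu - (-1024)) / 1, raw + 0)
  hu2 <- to_hounsfield(raw, 2.5, 7)
  expect_equal((hu2 - 7) / 2.5, raw + 0)
})

test_that("HU conversion rejects degenerate input and zero slope", {
  expect_error(to_hounsfield(matrix(numeric(0), 0, 0), 1, 0), "invalid input")
  expect_error(to_hounsfield(matrix(1, 2, 2), 0, -1024), "slope")
})

test_that("DICOM write/read round-trips HU grids bit-exactly", {
  ph <- generate_phantom_study(quick_params(21, n_slices = 2), render = TRUE)
  s <- ph$study$slices[[1]]
  path <- tempfile(fileext = ".dcm")
  write_dicom_slice(s, path, instance_number = 1L)
  r <- read_slice(path)
  expect_identical(r$hu_image, s$hu_image)
  expect_equal(r$pixel_spacing_mm, s$pixel_spacing_mm)
  expect_equal(r$slice_thickness_mm, s$slice_thickness_mm)
  expect_equal(r$z_position_mm, s$z_position_mm)
  expect_identical(r$patient_id, s$patient_id)
})

test_that("pixel spacing metadata survives the round trip exactly", {
  ph <- generate_phantom_study(
    quick_params(22, n_slices = 2, pixel_spacing_mm = c(0.7, 0.7)),
    render = TRUE)
  path <- tempfile(fileext = ".dcm")
  write_dicom_slice(ph$study$slices[[1]], path)
  expect_identical(read_slice(path)$pixel_spacing_mm, c(0.7, 0.7))
})

test_that("reader names the missing tag and rejects non-512 geometry", {
  # hand-assemble files with internal codec pieces
  el <- l3comp:::dcm_element
  preamble <- c(rep(as.raw(0), 128), charToRaw("DICM"))
  meta_body <- c(
    el(0x0002, 0x0010, "UI", l3comp:::TS_EXPLICIT_VR_LE))
  meta <- c(el(0x0002, 0x0000, "UL", length(meta_body)), meta_body)
  base_ds <- function(rows, cols, with_spacing = TRUE) {
    pix <- writeBin(integer(as.integer(rows) * as.integer(cols)), raw(),
                    size = 2, endian = "little")
    c(el(0x0018, 0x0050, "DS", "5"),
      el(0x0020, 0x0032, "DS", "0\\0\\0"),
      if (with_spacing) el(0x0028, 0x0030, "DS", "0.8\\0.8"),
      el(0x0028, 0x0010, "US", rows), el(0x0028, 0x0011, "US", cols),
      el(0x0028, 0x0100, "US", 16L), el(0x0028, 0x0103, "US", 1L),
      el(0x0028, 0x1052, "DS", "-1024"), el(0x0028, 0x1053, "DS", "1"),
      el(0x7FE0, 0x0010, "OW", pix))
  }
  f1 <- tempfile(fileext = ".dcm")
  writeBin(c(preamble, meta, base_ds(512L, 512L, with_spacing = FALSE)), f1)
  expect_error(read_slice(f1), "PixelSpacing")
  f2 <- tempfile(fileext = ".dcm")
  writeBin(c(preamble, meta, base_ds(256L, 256L)), f2)
  expect_error(read_slice(f2), "geometry error")
})

test_that("load_study sorts by z, sets the designated mid slice, and checks counts", {
  ph <- generate_phantom_study(quick_params(23, n_slices = 10L),
                               render = TRUE)
  dir <- file.path(tempdir(), "study23")
  unlink(dir, recursive = TRUE)
  paths <- write_dicom_series(ph$study, dir)
  expect_length(paths, 10L)
  # designate the 6th slice by z as mid
  st <- load_study(sample(paths), mid_designation = basename(paths[6]),
                   sex = "M", age_years = 61)
  expect_s3_class(st, "patient_study")
  expect_identical(st$mid_index, 6L)
  expect_true(st$slices[[6]]$is_mid)
  expect_identical(sum(vapply(st$slices, function(s) s$is_mid, logical(1))), 1L)
  z <- vapply(st$slices, function(s) s$z_position_mm, numeric(1))
  expect_true(all(diff(z) > 0))
  expect_error(load_study(paths[1], basename(paths[1]), "M", 60),
               "insufficient data")
  expect_error(load_study(paths, "nonexistent.dcm", "M", 60),
               "designation error")
})

test_that("duplicate z positions are an ordering error", {
  ph <- generate_phantom_study(quick_params(24, n_slices = 2), render = TRUE)
  dir <- file.path(tempdir(), "dupz")
  unlink(dir, recursive = TRUE)
  dir.create(dir)
  s1 <- ph$study$slices[[1]]
  s2 <- ph$study$slices[[2]]
  s2$z_position_mm <- s1$z_position_mm
  write_dicom_slice(s1, file.path(dir, "a.dcm"))
  write_dicom_slice(s2, file.path(dir, "b.dcm"))
  expect_error(load_study(file.path(dir, c("a.dcm", "b.dcm")), "a.dcm",
                          "F", 50), "ordering error")
})

test_that("manifest round-trips and load_cohort rebuilds every study", {
  dir <- file.path(tempdir(), "coh_manifest")
  unlink(dir, recursive = TRUE)
  coh <- generate_cohort(1, 1, seed = 9, render = TRUE,
                         base = list(n_slices = 2L),
                         n_slices_choices = c(2L, 2L),
                         n_slices_weights = c(1, 1))
  for (ph in coh) write_dicom_series(ph$study, dir)
  man <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_setequal(unique(man$patient_id), c("P001", "P002"))
  studies <- load_cohort(file.path(dir, "manifest.tsv"))
  expect_length(studies, 2L)
  expect_identical(studies[["P002"]]$sex, "male")
  expect_identical(studies[["P001"]]$mid_index,
                   coh[[1]]$truth$params$mid_index)
})
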