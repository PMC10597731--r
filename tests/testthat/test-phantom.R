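test_that("phantom generation is a pure function of its parameters", {
  p <- quick_params(51, n_slices = 3)
  a <- generate_phantom_study(p, render = TRUE)
  b <- generate_phantom_study(p, render = TRUE)
  expect_identical(a$study$slices[[2]]$hu_image, b$study$slices[[2]]$hu_image)
  expect_identical(truth_measures(a), truth_measures(b))
  # byte-level DICOM determinism
  f1 <- tempfile(); f2 <- tempfile()
  write_dicom_slice(a$study$slices[[1]], f1)
  write_dicom_slice(b$study$slices[[1]], f2)
  expect_identical(readBin(f1, raw(), file.size(f1)),
                   readBin(f2, raw(), file.size(f2)))
})

test_that("truth measures are identical whether or not pixels are rendered", {
  p <- quick_params(52, n_slices = 3)
  expect_identical(truth_measures(generate_phantom_study(p, render = FALSE)),
                   truth_measures(generate_phantom_study(p, render = TRUE)))
})

test_that("zero-noise phantoms have exactly the tissue means", {
  ph <- generate_phantom_study(quick_params(53, n_slices = 2,
                                            noiseless = TRUE), render = TRUE)
  hu <- ph$study$slices[[1]]$hu_image
  gt <- ph$truth$masks[[1]]
  codes <- tissue_labels()
  expect_identical(unique(hu[gt == codes[["SM"]]]), 40)
  expect_identical(unique(hu[gt == codes[["VAT"]]]), -90)
  expect_identical(unique(hu[gt == codes[["SAT"]]]), -105)
})

test_that("rasterised ground-truth areas track the analytic ellipse rings", {
  ph <- generate_phantom_study(quick_params(54, n_slices = 3,
                                            noiseless = TRUE), render = TRUE)
  tr <- truth_measures(ph)
  px_cm2 <- prod(ph$truth$params$pixel_spacing_mm) / 100
  for (i in seq_along(ph$truth$masks)) {
    gt <- ph$truth$masks[[i]]
    for (t in c("SM", "VAT", "SAT")) {
      rast <- sum(gt == tissue_labels()[[t]]) * px_cm2
      want <- tr$area_cm2[tr$slice_index == i & tr$tissue == t]
      expect_lt(abs(rast - want) / want, 0.02,
                label = sprintf("%s slice %d", t, i))
    }
  }
})

test_that("VAT-only modulation shows up in truth APD at the programmed size", {
  amp <- 0.1
  p <- quick_params(55, n_slices = 9L, noiseless = TRUE,
                    body_amp = 0, sat_amp = 0, vat_amp = amp)
  tr <- truth_measures(generate_phantom_study(p, render = FALSE))
  tr_v <- tr[tr$tissue == "VAT", ]
  apd <- avg_percent_difference(tr_v$area_cm2[tr_v$is_mid],
                                tr_v$area_cm2[!tr_v$is_mid])
  prof <- (seq_len(9) - 5) / 4
  expect_equal(apd, amp * mean(abs(prof[-5])) * 100, tolerance = 1e-9)
  # SM and SAT areas are untouched by VAT modulation
  for (t in c("SM", "SAT")) {
    a <- tr$area_cm2[tr$tissue == t]
    expect_lt(diff(range(a)) / mean(a), 1e-12)
  }
})

test_that("cohort generation reproduces the sex orderings on ground truth", {
  coh <- generate_cohort(30, 30, seed = 56)
  tm <- cohort_truth_measures(coh)
  mid <- tm$measures[tm$measures$is_mid, ]
  mid <- merge(mid, tm$patients[c("patient_id", "sex")], by = "patient_id")
  med <- function(t, s) median(mid$area_cm2[mid$tissue == t & mid$sex == s])
  expect_gt(med("SAT", "female"), med("SAT", "male"))
  expect_lt(med("SM", "female"), med("SM", "male"))
  expect_lt(med("VAT", "female"), med("VAT", "male"))
  # slice counts follow the configured distribution support
  ns <- vapply(coh, function(ph) ph$truth$params$n_slices, integer(1))
  expect_true(all(ns >= 8 & ns <= 12))
  expect_identical(anyDuplicated(vapply(coh, function(ph)
    ph$truth$params$patient_id, character(1))), 0L)
})

test_that("the same master seed reproduces the whole cohort", {
  c1 <- generate_cohort(2, 2, seed = 57)
  c2 <- generate_cohort(2, 2, seed = 57)
  expect_identical(cohort_truth_measures(c1), cohort_truth_measures(c2))
})

test_that("invalid phantom parameters are rejected", {
  expect_error(phantom_params(1, sat_thick = -1), "parameter error")
  expect_error(phantom_params(1, vat_frac = 1.2), "parameter error")
  expect_error(phantom_params(1, body_a = 260), "parameter error")
  expect_error(phantom_params(1, hu_mean = c(SM = 200, VAT = -90, SAT = -105,
                                             organ = 20, gas = -1000)),
               "parameter error")
  expect_error(generate_cohort(0, 5, seed = 1), "parameter error")
  se <- default_sex_effects(); se$female$sat <- -2
  expect_error(generate_cohort(2, 2, seed = 1, sex_effects = se),
               "parameter error")
})

test_that("a written series has one file per slice plus manifest rows", {
  ph <- generate_phantom_study(quick_params(58, n_slices = 10L),
                               render = TRUE)
  dir <- file.path(tempdir(), "series58")
  unlink(dir, recursive = TRUE)
  paths <- write_dicom_series(ph$study, dir)
  expect_length(paths, 10L)
  expect_true(all(file.exists(paths)))
  man <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(nrow(man), 10L)
  expect_equal(sum(man$is_mid), 1L)
})
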