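test_that("average percent difference matches hand-computed values", {
  expect_equal(avg_percent_difference(200, c(180, 220, 200)), 20 / 3)
  expect_equal(avg_percent_difference(-100, -90), 10)
  expect_equal(avg_percent_difference(100, c(100, 100)), 0)
})

test_that("average percent difference is scale-invariant and zero iff identical", {
  set.seed(7)
  for (i in 1:50) {
    mid <- rnorm(1, 100, 30)
    others <- rnorm(sample(1:8, 1), 100, 30)
    cc <- rnorm(1, 0, 5); if (cc == 0) cc <- 1
    expect_equal(avg_percent_difference(mid, others),
                 avg_percent_difference(cc * mid, cc * others))
    expect_gte(avg_percent_difference(mid, others), 0)
  }
  expect_equal(avg_percent_difference(37, rep(37, 5)), 0)
  expect_gt(avg_percent_difference(37, c(37, 37.1)), 0)
})

test_that("undefined mid or empty comparison set yields the NA marker", {
  expect_identical(avg_percent_difference(0, c(1, 2)), NA_real_)
  expect_identical(avg_percent_difference(NA_real_, c(1, 2)), NA_real_)
  expect_identical(avg_percent_difference(10, numeric(0)), NA_real_)
  expect_identical(avg_percent_difference(10, c(NA_real_, NA_real_)),
                   NA_real_)
})

test_that("cohort summary gives interpolated quartiles and handles degenerate input", {
  s <- cohort_summary(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3); expect_equal(s$iqr_low, 2)
  expect_equal(s$iqr_high, 4)
  s1 <- cohort_summary(7)
  expect_equal(unlist(s1[c("median", "iqr_low", "iqr_high")]),
               c(median = 7, iqr_low = 7, iqr_high = 7))
  expect_error(cohort_summary(c(NA_real_, NA_real_)), "insufficient data")
  # permutation invariance
  set.seed(8)
  v <- rnorm(31)
  expect_identical(cohort_summary(v), cohort_summary(sample(v)))
})

test_that("sample quartiles converge to analytic quantiles", {
  set.seed(9)
  v <- runif(1000, 0, 10)  # quartiles 2.5 / 5 / 7.5
  s <- cohort_summary(v)
  expect_lt(abs(s$median - 5), 0.35)
  expect_lt(abs(s$iqr_low - 2.5), 0.35)
  expect_lt(abs(s$iqr_high - 7.5), 0.35)
})

test_that("Mann-Whitney matches the enumeration example and tie contract", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6), mode = "exact")
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)  # 2 extreme assignments of choose(6,3)=20
  expect_equal(mann_whitney(c(5, 5, 5), c(5, 5, 5), mode = "exact")$p, 1)
  expect_error(mann_whitney(numeric(0), 1), "invalid input")
})

test_that("exact p equals the brute-force enumeration oracle, including ties", {
  set.seed(10)
  for (i in 1:25) {
    na_ <- sample(2:6, 1); nb_ <- sample(2:6, 1)
    vals <- if (i %% 2) sample(1:4, na_ + nb_, replace = TRUE) else
      rnorm(na_ + nb_)
    a <- vals[seq_len(na_)]; b <- vals[-seq_len(na_)]
    got <- mann_whitney(a, b, mode = "exact")
    want <- bf_mann_whitney(a, b)
    expect_equal(got$p, want$p, tolerance = 1e-12)
    expect_equal(got$U, want$U)
    # complement identity
    expect_equal(got$U + mann_whitney(b, a, mode = "exact")$U, na_ * nb_)
  }
})

test_that("exact p agrees with wilcox.test's exact p when there are no ties", {
  set.seed(12)
  for (i in 1:20) {
    a <- rnorm(sample(3:7, 1)); b <- rnorm(sample(3:7, 1))
    expect_equal(mann_whitney(a, b, mode = "exact")$p,
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("asymptotic p tracks exact p closely at small n", {
  set.seed(13)
  gaps <- replicate(100, {
    a <- rnorm(6); b <- rnorm(6)
    abs(mann_whitney(a, b, "exact")$p - mann_whitney(a, b, "asymptotic")$p)
  })
  expect_lt(max(gaps), 0.03)
})

test_that("auto mode switches between exact and asymptotic at the size cutoff", {
  expect_identical(mann_whitney(rnorm(8), rnorm(12))$mode, "exact")
  expect_identical(mann_whitney(rnorm(9), rnorm(9))$mode, "asymptotic")
  expect_identical(mann_whitney(rnorm(5), rnorm(13))$mode, "asymptotic")
})

test_that("variability records propagate undefined measures per measure", {
  # two patients, 2 slices each; patient B has zero VAT on the mid slice
  mk <- function(pid, vat_mid) {
    expand <- expand.grid(slice_index = 1:2, tissue = c("SM", "VAT", "SAT"),
                          stringsAsFactors = FALSE)
    expand$patient_id <- pid
    expand$is_mid <- expand$slice_index == 1
    expand$area_cm2 <- ifelse(expand$tissue == "VAT" & expand$is_mid,
                              vat_mid, 100 + expand$slice_index)
    expand$radiodensity_hu <- ifelse(
      expand$tissue == "VAT" & expand$is_mid & vat_mid == 0, NA_real_, -90)
    expand
  }
  measures <- rbind(mk("A", vat_mid = 50), mk("B", vat_mid = 0))
  pats <- data.frame(patient_id = c("A", "B"), sex = c("female", "male"))
  rec <- build_variability_records(measures, pats)
  expect_equal(nrow(rec), 12)
  recB <- rec[rec$patient_id == "B", ]
  expect_true(is.na(recB$apd[recB$measure == "VAT_area"]))
  expect_true(is.na(recB$apd[recB$measure == "VAT_radiodensity"]))
  expect_false(anyNA(recB$apd[!grepl("VAT", recB$measure)]))
  # patient A, VAT area: mid 50, other 102 -> 104%
  recA <- rec[rec$patient_id == "A", ]
  expect_equal(recA$apd[recA$measure == "VAT_area"], 104)
})

test_that("a two-slice study yields a record from a single comparison", {
  coh <- generate_cohort(1, 1, seed = 14, base = list(n_slices = 2L),
                         n_slices_choices = c(2L, 2L),
                         n_slices_weights = c(1, 1))
  tm <- cohort_truth_measures(coh)
  rec <- build_variability_records(tm$measures, tm$patients)
  expect_equal(nrow(rec), 12)
  expect_false(anyNA(rec$apd))
})

test_that("sex comparison summarises all six measures and needs both sexes", {
  coh <- generate_cohort(10, 10, seed = 15)
  tm <- cohort_truth_measures(coh)
  rec <- build_variability_records(tm$measures, tm$patients)
  summ <- sex_comparison(rec)
  expect_equal(nrow(summ), 18)  # 6 measures x 3 groups
  expect_true(all(summ$iqr_low <= summ$median & summ$median <= summ$iqr_high))
  expect_identical(summ$significant, summ$p_value < 0.05)
  only_f <- rec[rec$sex == "female", ]
  expect_error(sex_comparison(only_f), "insufficient data")
})
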