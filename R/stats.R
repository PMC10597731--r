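# Mid-L3 vs non-mid-L3 variability statistics: per-patient average percent
# difference, cohort median/IQR summaries, and the Mann-Whitney sex comparison
# with an exact small-sample mode.

MEASURES <- c("SM_area", "SM_radiodensity", "VAT_area", "VAT_radiodensity",
              "SAT_area", "SAT_radiodensity")

#' Average percent difference between the mid-L3 slice and the other slices
#'
#' For one body-composition measure of one patient: the mean over all non-mid
#' slices of \code{|(value - mid) / mid| * 100}. Negative denominators
#' (radiodensities) are handled by the absolute value. Undefined inputs (a
#' missing or zero mid value, or no defined non-mid values) yield \code{NA},
#' which downstream summaries exclude per measure; this is a recorded marker,
#' not an error.
#'
#' @param mid_value Measure on the designated mid-L3 slice.
#' @param other_values Numeric vector of the measure on the non-mid slices
#'   (NAs are dropped).
#' @return Non-negative percent, or \code{NA_real_} when undefined.
#' @examples
#' avg_percent_difference(200, c(180, 220, 200))  # 6.666...
#' avg_percent_difference(-100, -90)              # 10
#' @export
avg_percent_difference <- function(mid_value, other_values) {
  others <- other_values[!is.na(other_values)]
  if (length(mid_value) != 1L) stop("mid_value must be a scalar", call. = FALSE)
  if (is.na(mid_value) || mid_value == 0 || length(others) == 0L)
    return(NA_real_)
  mean(abs((others - mid_value) / mid_value)) * 100
}

#' Median and interquartile range of a cohort of values
#'
#' Percentiles use linear interpolation between order statistics
#' (\code{\link[stats]{quantile}} type 7). NAs are dropped first.
#'
#' @param values Numeric vector with at least one defined value.
#' @return List with \code{n}, \code{median}, \code{iqr_low} (25th percentile)
#'   and \code{iqr_high} (75th percentile).
#' @export
cohort_summary <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0L)
    stop("insufficient data: no defined values to summarise", call. = FALSE)
  q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
  list(n = length(v), median = q[2], iqr_low = q[1], iqr_high = q[3])
}

# U statistic, standard convention (wilcox.test's W): number of (a, b) pairs
# with a > b, plus half the tied pairs. Computed through pooled mid-ranks so
# ties are exact.
mw_u_statistic <- function(a, b) {
  r <- rank(c(a, b))
  na <- length(a)
  sum(r[seq_len(na)]) - na * (na + 1) / 2
}

mw_exact_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  # 2x the mid-ranks are integers even with ties -> exact integer arithmetic
  r2 <- as.integer(round(2 * rank(pooled)))
  n <- na + nb
  u_obs2 <- as.integer(round(2 * mw_u_statistic(a, b)))
  mu2 <- na * nb            # 2 * (na*nb/2)
  dev_obs <- abs(u_obs2 - mu2)
  idx <- combn(n, na)
  const <- na * (na + 1L)
  u2 <- colSums(matrix(r2[idx], nrow = na)) - const
  mean(abs(u2 - mu2) >= dev_obs)
}

mw_asymptotic_p <- function(a, b, continuity = TRUE) {
  na <- length(a); nb <- length(b); n <- na + nb
  u <- mw_u_statistic(a, b)
  mu <- na * nb / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- abs(u - mu)
  if (continuity) z <- max(0, z - 0.5)
  min(1, 2 * pnorm(-z / sqrt(sigma2)))
}

#' Mann-Whitney U test (exact and asymptotic modes)
#'
#' U counts the (a, b) pairs with a > b plus half the tied pairs (the
#' convention of \code{\link[stats]{wilcox.test}}'s W; the complement
#' identity \code{U + U' = n_a n_b} relates the two orientations). The exact
#' mode enumerates the permutation distribution of U over all assignments of
#' the pooled values to the two groups (valid under ties); the asymptotic mode
#' uses the normal approximation with tie-corrected variance and a 0.5
#' continuity correction. \code{"auto"} picks the exact mode when
#' \code{min(n) <= 8} and neither group exceeds 12. Two-sided p-values
#' throughout.
#'
#' @param group_a,group_b Non-empty numeric vectors (NAs dropped).
#' @param mode "auto", "exact" or "asymptotic".
#' @return List with \code{U}, \code{p}, \code{mode} (mode actually used) and
#'   the group sizes.
#' @export
mann_whitney <- function(group_a, group_b,
                         mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (length(a) == 0L || length(b) == 0L)
    stop("invalid input: both groups must be non-empty", call. = FALSE)
  if (mode == "auto")
    mode <- if (min(length(a), length(b)) <= 8L &&
                max(length(a), length(b)) <= 12L) "exact" else "asymptotic"
  p <- if (mode == "exact") mw_exact_p(a, b) else mw_asymptotic_p(a, b)
  list(U = mw_u_statistic(a, b), p = p, mode = mode,
       n_a = length(a), n_b = length(b))
}

#' Per-patient variability records from per-slice measures
#'
#' Computes, for every patient and each of the six measures (SM/VAT/SAT area
#' and radiodensity), the \code{\link{avg_percent_difference}} between the
#' mid-L3 slice and all non-mid slices.
#'
#' @param measures Data frame of per-slice measures as produced by
#'   \code{\link{measure_study}} (columns patient_id, slice_index, is_mid,
#'   tissue, area_cm2, radiodensity_hu).
#' @param patients Data frame mapping \code{patient_id} to \code{sex}.
#' @return Data frame with columns patient_id, sex, measure, apd (NA = the
#'   undefined marker for that measure).
#' @export
build_variability_records <- function(measures, patients) {
  need <- c("patient_id", "slice_index", "is_mid", "tissue", "area_cm2",
            "radiodensity_hu")
  if (!all(need %in% names(measures)))
    stop("measures is missing columns: ",
         paste(setdiff(need, names(measures)), collapse = ", "),
         call. = FALSE)
  patients$sex <- normalize_sex(patients$sex)
  sex_of <- setNames(patients$sex, patients$patient_id)
  out <- list()
  for (pid in unique(measures$patient_id)) {
    m <- measures[measures$patient_id == pid, , drop = FALSE]
    if (sum(m$is_mid) == 0L)
      stop("patient ", pid, " has no mid-L3 slice in measures", call. = FALSE)
    for (tis in TISSUES) {
      mt <- m[m$tissue == tis, , drop = FALSE]
      for (metric in c("area", "radiodensity")) {
        col <- if (metric == "area") "area_cm2" else "radiodensity_hu"
        mid <- mt[[col]][mt$is_mid][1]
        # a zero-area mid slice means the tissue is absent at mid-L3: the
        # percent difference is undefined there, as is its radiodensity
        others <- mt[[col]][!mt$is_mid]
        out[[length(out) + 1L]] <- data.frame(
          patient_id = pid,
          sex = unname(sex_of[pid]),
          measure = paste(tis, metric, sep = "_"),
          apd = avg_percent_difference(mid, others),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Sex-stratified cohort summary of variability records
#'
#' For each of the six measures: median and IQR of the per-patient average
#' percent differences in all patients, in females and in males, plus the
#' two-sided Mann-Whitney male-vs-female p-value. Undefined (NA) records are
#' excluded per measure, not per patient. No multiple-testing correction is
#' applied across the six measures.
#'
#' @param records Data frame from \code{\link{build_variability_records}}.
#' @param mode Mann-Whitney mode, see \code{\link{mann_whitney}}.
#' @param alpha Significance level (default 0.05).
#' @param value_col Name of the value column to summarise (default "apd";
#'   set to e.g. "value" to summarise raw mid-L3 measures).
#' @return Data frame with columns measure, group (all/female/male), n,
#'   median, iqr_low, iqr_high, p_value, significant. The p-value of the
#'   male-vs-female comparison is repeated on each row of its measure.
#' @export
sex_comparison <- function(records, mode = "auto", alpha = 0.05,
                           value_col = "apd") {
  if (!all(c("sex", "measure", value_col) %in% names(records)))
    stop("records must have sex, measure and ", value_col, " columns",
         call. = FALSE)
  sexes <- unique(records$sex)
  if (!all(c("female", "male") %in% sexes))
    stop("insufficient data: both sexes must be represented", call. = FALSE)
  out <- list()
  for (meas in unique(records$measure)) {
    rm_ <- records[records$measure == meas, , drop = FALSE]
    vals <- list(all = rm_[[value_col]],
                 female = rm_[[value_col]][rm_$sex == "female"],
                 male = rm_[[value_col]][rm_$sex == "male"])
    mw <- mann_whitney(vals$male[!is.na(vals$male)],
                       vals$female[!is.na(vals$female)], mode = mode)
    for (g in names(vals)) {
      cs <- cohort_summary(vals[[g]])
      out[[length(out) + 1L]] <- data.frame(
        measure = meas, group = g, n = cs$n, median = cs$median,
        iqr_low = cs$iqr_low, iqr_high = cs$iqr_high,
        p_value = mw$p, significant = mw$p < alpha,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Sex-stratified summary of raw mid-L3 measures
#'
#' The companion of \code{\link{sex_comparison}} for the measures themselves
#' (not their variability): median/IQR of each measure on the designated
#' mid-L3 slice in all patients and by sex, with male-vs-female Mann-Whitney
#' p-values.
#'
#' @inheritParams build_variability_records
#' @inheritParams sex_comparison
#' @return Data frame in the same schema as \code{\link{sex_comparison}}.
#' @export
mid_l3_summary <- function(measures, patients, mode = "auto", alpha = 0.05) {
  mid <- measures[measures$is_mid, , drop = FALSE]
  patients$sex <- normalize_sex(patients$sex)
  sex_of <- setNames(patients$sex, patients$patient_id)
  recs <- list()
  for (metric in c("area", "radiodensity")) {
    col <- if (metric == "area") "area_cm2" else "radiodensity_hu"
    recs[[metric]] <- data.frame(
      patient_id = mid$patient_id,
      sex = unname(sex_of[mid$patient_id]),
      measure = paste(mid$tissue, metric, sep = "_"),
      apd = mid[[col]],
      stringsAsFactors = FALSE)
  }
  recs <- do.call(rbind, recs)
  recs <- recs[order(match(recs$measure, MEASURES)), , drop = FALSE]
  sex_comparison(recs, mode = mode, alpha = alpha)
}
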