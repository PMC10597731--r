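# Model-style front end: fit the mid-L3 vs whole-L3 variability analysis and
# return a classed object with the usual accessor methods.

#' Fit the mid-L3 vs whole-L3 variability analysis
#'
#' The central estimator of the package. For every patient it computes the
#' average percent difference (APD) between the designated mid-L3 slice and
#' all other L3 slices for six body-composition measures (SM/VAT/SAT area and
#' radiodensity), summarises the cohort by median and IQR overall and by sex,
#' and tests for a male-female difference in each measure's APD with a
#' two-sided Mann-Whitney test.
#'
#' @param measures Per-slice measures data frame from
#'   \code{\link{measure_study}} (or the phantom generator's ground truth).
#' @param patients Data frame mapping \code{patient_id} to \code{sex}.
#' @param mode Mann-Whitney mode ("auto", "exact", "asymptotic").
#' @param alpha Significance level for flagging (default 0.05; no
#'   multiple-testing correction across the six measures).
#'
#' @return Object of class \code{l3_variability} with components
#'   \code{records} (per-patient APDs), \code{summary} (sex-stratified
#'   median/IQR/p table), \code{alpha}, \code{mode} and \code{call}. Methods:
#'   \code{print}, \code{summary}, \code{coef} (overall median APD per
#'   measure), \code{plot} (APD by sex per measure).
#' @examples
#' \donttest{
#' coh <- generate_cohort(n_female = 8, n_male = 8, seed = 1)
#' tm <- cohort_truth_measures(coh)
#' fit <- l3_variability(tm$measures, tm$patients)
#' fit
#' coef(fit)
#' }
#' @export
l3_variability <- function(measures, patients, mode = "auto", alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  records <- build_variability_records(measures, patients)
  summ <- sex_comparison(records, mode = mode, alpha = alpha)
  structure(list(records = records, summary = summ, alpha = alpha,
                 mode = mode, call = match.call()),
            class = "l3_variability")
}

#' @export
print.l3_variability <- function(x, ...) {
  n_pat <- length(unique(x$records$patient_id))
  n_f <- length(unique(x$records$patient_id[x$records$sex == "female"]))
  cat(sprintf(
    "Mid-L3 vs whole-L3 body-composition variability (%d patients: %d F, %d M)\n",
    n_pat, n_f, n_pat - n_f))
  cat("Average percent difference, median% (IQR); Mann-Whitney male vs female\n\n")
  print(render_tables(x$summary, percent = TRUE), row.names = FALSE)
  invisible(x)
}

#' @export
summary.l3_variability <- function(object, ...) {
  out <- object$summary
  class(out) <- c("summary.l3_variability", class(out))
  out
}

#' @export
print.summary.l3_variability <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.l3_variability <- function(object, ...) {
  s <- object$summary[object$summary$group == "all", , drop = FALSE]
  setNames(s$median, s$measure)
}

#' @export
plot.l3_variability <- function(x, ...) {
  meas <- unique(x$records$measure)
  op <- par(mfrow = c(2, ceiling(length(meas) / 2)), mar = c(3, 4, 2, 1))
  on.exit(par(op))
  for (m in meas) {
    r <- x$records[x$records$measure == m & !is.na(x$records$apd), ]
    boxplot(apd ~ sex, data = r, ylab = "avg % difference", main = m, ...)
  }
  invisible(x)
}

#' Format a summary table the way clinical papers print it
#'
#' Renders each group cell as \code{"median (q25-q75)"} (with a percent sign
#' when \code{percent = TRUE}) and p-values as \code{"<0.001"} below 1e-3,
#' three decimals below 0.01, else two decimals.
#'
#' @param summaries Data frame from \code{\link{sex_comparison}} or
#'   \code{\link{mid_l3_summary}}.
#' @param percent Append a percent sign to the median (used for APD tables).
#' @return Data frame with one row per measure and columns all, female, male,
#'   p_value.
#' @export
render_tables <- function(summaries, percent = FALSE) {
  if (is.null(summaries) || nrow(summaries) == 0L)
    stop("insufficient data: no summaries to render", call. = FALSE)
  fmt_cell <- function(med, lo, hi)
    sprintf("%.2f%s (%.2f–%.2f)", med, if (percent) "%" else "", lo, hi)
  rows <- list()
  for (meas in unique(summaries$measure)) {
    s <- summaries[summaries$measure == meas, , drop = FALSE]
    cell <- function(g) {
      r <- s[s$group == g, , drop = FALSE]
      if (nrow(r) == 0L) return(NA_character_)
      fmt_cell(r$median, r$iqr_low, r$iqr_high)
    }
    rows[[meas]] <- data.frame(
      measure = meas, all = cell("all"), female = cell("female"),
      male = cell("male"), p_value = format_p(s$p_value[1]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format a p-value for reporting
#'
#' @param p Numeric p-value.
#' @return Character: \code{"<0.001"} below 0.001, 3 decimals below 0.01,
#'   otherwise 2 decimals.
#' @export
format_p <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) return("<0.001")
  if (p < 0.01) return(sprintf("%.3f", p))
  sprintf("%.2f", p)
}
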