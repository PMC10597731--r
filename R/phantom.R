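# Parametric axial abdominal CT phantoms with analytic ground truth.
#
# Geometry is a nest of concentric ellipses (outside -> in): SAT ring, muscle
# (SM) ring, visceral cavity. The cavity is a VAT ring around a bowel-gas core
# (-1000 HU, filled as an interior air pocket by body_mask), plus a few small
# organ blobs at soft-tissue HU that are deliberately below the segmenter's
# minimum-object size. Elliptical rings keep every tissue area available in
# closed form, so the whole pipeline can be checked against exact oracles.

#' Parameters of one synthetic abdominal phantom study
#'
#' Defaults emulate the acquisition characteristics of a clinical L3 stack:
#' 512 x 512 pixels, ~10 slices, 1-8 mm slice thickness, and tissue HU
#' distributions inside the Alberta threshold ranges (SM 40 +/- 10, VAT
#' -90 +/- 15, SAT -105 +/- 15 HU; soft-tissue blobs 20 +/- 10; gas -1000).
#' Slice geometry is modulated along z by a monotone profile that is zero at
#' the mid slice, mimicking mid-L3 vs non-mid-L3 anatomical change: body axes
#' scale by \code{1 + body_amp * profile}, SAT ring thickness by
#' \code{1 + sat_amp * profile} and the cavity VAT fraction by
#' \code{1 + vat_amp * profile}.
#'
#' @param seed Integer seed; all randomness is a pure function of it.
#' @param patient_id,sex,age_years Patient metadata.
#' @param n_slices Number of slices (>= 2).
#' @param mid_index 1-based mid-L3 slice (default: central slice).
#' @param body_a,body_b Body ellipse semi-axes at mid slice, pixels.
#' @param sat_thick,sm_thick SAT and muscle ring thicknesses, pixels.
#' @param vat_frac Fraction of the visceral cavity occupied by VAT, (0, 1).
#' @param hu_mean,hu_sd Named numeric vectors (SM, VAT, SAT, organ, gas) of
#'   per-tissue HU means and per-pixel noise SDs.
#' @param drift_sd SD (HU) of the per-slice radiodensity drift added to each
#'   tissue mean; this is what makes radiodensity vary slice to slice.
#' @param body_amp,sat_amp,vat_amp Signed modulation amplitudes (fractional
#'   change at the stack ends).
#' @param pixel_spacing_mm,slice_thickness_mm Geometry metadata.
#' @param center Phantom centre (row, col), pixels.
#' @param n_organ,organ_r Number and pixel radius of small organ blobs in the
#'   gas core.
#' @param margin Minimum gap (px) between the body ellipse and the image edge;
#'   violated geometry is rejected.
#'
#' @return Validated list of class \code{phantom_params}.
#' @export
phantom_params <- function(seed,
                           patient_id = "P001", sex = "male", age_years = 60,
                           n_slices = 10L, mid_index = NULL,
                           body_a = 170, body_b = 125,
                           sat_thick = 18, sm_thick = 20, vat_frac = 0.55,
                           hu_mean = c(SM = 40, VAT = -90, SAT = -105,
                                       organ = 20, gas = -1000),
                           hu_sd = c(SM = 10, VAT = 15, SAT = 15,
                                     organ = 10, gas = 10),
                           drift_sd = 1,
                           body_amp = 0.04, sat_amp = 0.04, vat_amp = 0.10,
                           pixel_spacing_mm = c(0.9765625, 0.9765625),
                           slice_thickness_mm = 5,
                           center = c(256.5, 256.5),
                           n_organ = 3L, organ_r = 2,
                           margin = 10) {
  p <- list(seed = as.integer(seed), patient_id = patient_id,
            sex = normalize_sex(sex), age_years = age_years,
            n_slices = as.integer(n_slices),
            mid_index = if (is.null(mid_index)) (as.integer(n_slices) + 1L) %/% 2L
                        else as.integer(mid_index),
            body_a = body_a, body_b = body_b,
            sat_thick = sat_thick, sm_thick = sm_thick, vat_frac = vat_frac,
            hu_mean = hu_mean, hu_sd = hu_sd, drift_sd = drift_sd,
            body_amp = body_amp, sat_amp = sat_amp, vat_amp = vat_amp,
            pixel_spacing_mm = pixel_spacing_mm,
            slice_thickness_mm = slice_thickness_mm,
            center = center, n_organ = as.integer(n_organ), organ_r = organ_r,
            margin = margin, size = 512L)
  validate_phantom_params(p)
  structure(p, class = "phantom_params")
}

validate_phantom_params <- function(p) {
  if (p$n_slices < 2L)
    stop("parameter error: n_slices must be >= 2", call. = FALSE)
  if (p$mid_index < 1L || p$mid_index > p$n_slices)
    stop("parameter error: mid_index out of range", call. = FALSE)
  if (p$sat_thick <= 0 || p$sm_thick <= 0)
    stop("parameter error: ring thicknesses must be positive", call. = FALSE)
  if (p$vat_frac <= 0 || p$vat_frac >= 1)
    stop("parameter error: vat_frac must lie in (0, 1)", call. = FALSE)
  amp_max <- 1 + max(abs(p$body_amp), 0)
  for (g in phantom_slice_geometry(p)) {
    if (g$cav_a <= 0 || g$cav_b <= 0)
      stop("parameter error: rings do not nest (cavity degenerate)",
           call. = FALSE)
    if (p$center[1] - g$a < p$margin || p$center[1] + g$a > p$size - p$margin ||
        p$center[2] - g$b < p$margin || p$center[2] + g$b > p$size - p$margin)
      stop("parameter error: body ellipse does not fit the frame with margin ",
           p$margin, call. = FALSE)
  }
  thr <- alberta_thresholds()
  for (t in TISSUES) {
    m <- p$hu_mean[[t]]
    if (m <= thr[[t]][1] || m >= thr[[t]][2])
      stop("parameter error: HU mean for ", t,
           " must lie strictly inside its threshold range", call. = FALSE)
  }
  invisible(p)
}

# Monotone modulation profile along the stack: 0 at the mid slice, +/-1 at the
# far ends.
modulation_profile <- function(n, mid) {
  (seq_len(n) - mid) / max(mid - 1L, n - mid, 1L)
}

# Per-slice ellipse geometry (semi-axes in px) and VAT fraction. The VAT
# modulation acts on the VAT area itself (relative to the mid slice), not on
# the fraction of a cavity whose size already varies with the body scale:
# that keeps the programmed VAT offset equal to the VAT-area percent change,
# independent of the body-outline modulation.
phantom_slice_geometry <- function(p) {
  prof <- modulation_profile(p$n_slices, p$mid_index)
  cav_a_mid <- p$body_a - p$sat_thick * (1 + p$sat_amp * prof[p$mid_index]) -
    p$sm_thick
  cav_b_mid <- p$body_b - p$sat_thick * (1 + p$sat_amp * prof[p$mid_index]) -
    p$sm_thick
  vat_area_mid <- pi * cav_a_mid * cav_b_mid * p$vat_frac
  lapply(seq_len(p$n_slices), function(i) {
    scale <- 1 + p$body_amp * prof[i]
    a <- p$body_a * scale
    b <- p$body_b * scale
    sat <- p$sat_thick * (1 + p$sat_amp * prof[i])
    msc_a <- a - sat;            msc_b <- b - sat
    cav_a <- msc_a - p$sm_thick; cav_b <- msc_b - p$sm_thick
    vat_target <- vat_area_mid * (1 + p$vat_amp * prof[i])
    vf <- min(max(vat_target / (pi * cav_a * cav_b), 0.005), 0.98)
    gas_a <- cav_a * sqrt(1 - vf); gas_b <- cav_b * sqrt(1 - vf)
    list(a = a, b = b, msc_a = msc_a, msc_b = msc_b,
         cav_a = cav_a, cav_b = cav_b, gas_a = gas_a, gas_b = gas_b,
         vat_frac = vf)
  })
}

# Analytic tissue areas (cm^2) of one slice's geometry.
analytic_areas <- function(g, pixel_spacing_mm) {
  px_area <- pixel_spacing_mm[1] * pixel_spacing_mm[2] / 100
  c(SM = pi * (g$msc_a * g$msc_b - g$cav_a * g$cav_b) * px_area,
    VAT = pi * g$cav_a * g$cav_b * g$vat_frac * px_area,
    SAT = pi * (g$a * g$b - g$msc_a * g$msc_b) * px_area)
}

ellipse_mask <- function(size, center, a, b) {
  if (a <= 0 || b <= 0) return(matrix(FALSE, size, size))
  xs <- ((seq_len(size) - center[1]) / a)^2
  ys <- ((seq_len(size) - center[2]) / b)^2
  outer(xs, ys, "+") <= 1
}

# Rasterise one slice: list(hu = HU matrix, labels = ground-truth label mask).
render_phantom_slice <- function(p, g, slice_means) {
  size <- p$size; ctr <- p$center
  body <- ellipse_mask(size, ctr, g$a, g$b)
  msc <- ellipse_mask(size, ctr, g$msc_a, g$msc_b)
  cav <- ellipse_mask(size, ctr, g$cav_a, g$cav_b)
  gas <- ellipse_mask(size, ctr, g$gas_a, g$gas_b)
  sat_m <- body & !msc
  sm_m <- msc & !cav
  vat_m <- cav & !gas
  organ_m <- matrix(FALSE, size, size)
  if (p$n_organ > 0L && g$gas_a > 4 * p$organ_r && g$gas_b > 4 * p$organ_r) {
    offs <- seq(-1, 1, length.out = p$n_organ) * (g$gas_a - 2 * p$organ_r) * 0.6
    for (o in offs) {
      blob <- ellipse_mask(size, ctr + c(o, 0), p$organ_r, p$organ_r)
      organ_m <- organ_m | (blob & gas)
    }
  }
  gas_m <- gas & !organ_m

  fill <- function(hu, mask, mean_, sd_) {
    n <- sum(mask)
    if (n == 0L) return(hu)
    hu[mask] <- if (sd_ > 0) rnorm(n, mean_, sd_) else mean_
    hu
  }
  hu <- matrix(if (p$hu_sd[["gas"]] > 0)
                 rnorm(size * size, p$hu_mean[["gas"]], p$hu_sd[["gas"]])
               else p$hu_mean[["gas"]], size, size)
  hu <- fill(hu, sat_m, slice_means[["SAT"]], p$hu_sd[["SAT"]])
  hu <- fill(hu, sm_m, slice_means[["SM"]], p$hu_sd[["SM"]])
  hu <- fill(hu, vat_m, slice_means[["VAT"]], p$hu_sd[["VAT"]])
  hu <- fill(hu, organ_m, p$hu_mean[["organ"]], p$hu_sd[["organ"]])
  hu <- pmin(pmax(round(hu), -1100), 3100)

  labels <- matrix(LABEL_LEVELS[["background"]], size, size)
  labels[sm_m] <- LABEL_LEVELS[["SM"]]
  labels[vat_m] <- LABEL_LEVELS[["VAT"]]
  labels[sat_m] <- LABEL_LEVELS[["SAT"]]
  list(hu = hu, labels = labels)
}

#' Generate one synthetic phantom study with analytic ground truth
#'
#' Deterministic given \code{params$seed}. The ground truth carries, per
#' slice and tissue, the analytic ellipse-ring area (cm^2) and the generating
#' radiodensity (tissue mean plus that slice's drift), plus the rasterised
#' label masks when \code{render = TRUE}.
#'
#' @param params A \code{\link{phantom_params}} object.
#' @param render Rasterise HU images and masks (TRUE) or produce ground-truth
#'   measures only (FALSE; much faster, used for large statistical
#'   simulations).
#' @return List with \code{study} (a \code{patient_study}, or NULL when
#'   \code{render = FALSE}) and \code{truth} (list: params, measures data
#'   frame, masks).
#' @export
generate_phantom_study <- function(params, render = TRUE) {
  p <- validate_phantom_params(params)
  geoms <- phantom_slice_geometry(p)
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(p$seed)
  # Phase 1: per-slice radiodensity drift (same draws whether or not we
  # render, so truth measures are identical in both modes).
  drift <- matrix(if (p$drift_sd > 0) rnorm(3L * p$n_slices, 0, p$drift_sd)
                  else 0, nrow = p$n_slices, ncol = 3L,
                  dimnames = list(NULL, TISSUES), byrow = TRUE)
  measures <- list()
  for (i in seq_len(p$n_slices)) {
    ar <- analytic_areas(geoms[[i]], p$pixel_spacing_mm)
    measures[[i]] <- data.frame(
      patient_id = p$patient_id, slice_index = i,
      is_mid = i == p$mid_index, tissue = TISSUES,
      area_cm2 = unname(ar[TISSUES]),
      radiodensity_hu = unname(p$hu_mean[TISSUES] + drift[i, TISSUES]),
      stringsAsFactors = FALSE)
  }
  measures <- do.call(rbind, measures)

  study <- NULL
  masks <- NULL
  if (render) {
    slices <- vector("list", p$n_slices)
    masks <- vector("list", p$n_slices)
    for (i in seq_len(p$n_slices)) {
      means <- p$hu_mean[TISSUES] + drift[i, TISSUES]
      r <- render_phantom_slice(p, geoms[[i]], means)
      masks[[i]] <- r$labels
      slices[[i]] <- new_ct_slice(
        patient_id = p$patient_id, hu_image = r$hu,
        pixel_spacing_mm = p$pixel_spacing_mm,
        slice_thickness_mm = p$slice_thickness_mm,
        z_position_mm = (i - 1) * p$slice_thickness_mm)
    }
    study <- new_patient_study(p$patient_id, p$sex, p$age_years, slices,
                               p$mid_index)
  }
  list(study = study,
       truth = list(params = p, measures = measures, masks = masks))
}

#' Ground-truth per-slice measures of a phantom
#'
#' @param phantom Result of \code{\link{generate_phantom_study}}.
#' @return Data frame in the \code{\link{measure_study}} schema.
#' @export
truth_measures <- function(phantom) phantom$truth$measures

#' Default sex-effect multipliers for cohort generation
#'
#' Chosen so that, in expectation, females have a thicker SAT ring, a thinner
#' muscle ring, a slightly smaller body and a smaller visceral fat fraction
#' than males — the orderings reported for clinical mid-L3 cohorts — without
#' claiming to match any clinical cohort's numeric medians. The \code{*_amp}
#' entries multiply the slice-to-slice modulation amplitudes and default to 1
#' (no sex difference in variability, the null configuration).
#'
#' @return List with \code{female} and \code{male} multiplier lists.
#' @export
default_sex_effects <- function() {
  list(female = list(body = 0.97, sat = 1.90, sm = 0.85, vat_frac = 0.82,
                     body_amp = 1, sat_amp = 1, vat_amp = 1),
       male = list(body = 1, sat = 1, sm = 1, vat_frac = 1,
                   body_amp = 1, sat_amp = 1, vat_amp = 1))
}

#' Generate a synthetic cohort of phantom studies
#'
#' Per-patient seeds are derived reproducibly from the master seed; slice
#' counts follow a discrete triangular distribution on 8..12 (median 10, IQR
#' 9-11); patient geometry is jittered around the defaults and sex-effect
#' multipliers are applied to ring thicknesses, visceral fat fraction and
#' modulation amplitudes. Each patient's modulation amplitudes get a random
#' magnitude (uniform 0.5-1.5 times the base) and a random sign.
#'
#' @param n_female,n_male Patient counts (>= 1 each).
#' @param seed Master seed.
#' @param sex_effects See \code{\link{default_sex_effects}}; all multipliers
#'   must be positive.
#' @param render Rasterise pixel data (slow) or ground truth only.
#' @param base Named list of overrides passed to \code{\link{phantom_params}}
#'   (e.g. \code{list(hu_sd = c(SM = 5, VAT = 5, SAT = 5, organ = 5, gas = 5))}).
#' @param n_slices_choices,n_slices_weights Slice-count distribution.
#' @return List of phantom objects (as from
#'   \code{\link{generate_phantom_study}}), one per patient.
#' @export
generate_cohort <- function(n_female, n_male, seed,
                            sex_effects = default_sex_effects(),
                            render = FALSE, base = list(),
                            n_slices_choices = 8:12,
                            n_slices_weights = c(1, 2, 3, 2, 1)) {
  if (n_female < 1L || n_male < 1L)
    stop("parameter error: need at least one patient of each sex",
         call. = FALSE)
  for (s in c("female", "male"))
    if (any(unlist(sex_effects[[s]]) <= 0))
      stop("parameter error: sex-effect multipliers must be positive",
           call. = FALSE)
  n <- n_female + n_male
  sexes <- c(rep("female", n_female), rep("male", n_male))
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  seeds <- sample.int(2147483646L, n)
  n_slices <- n_slices_choices[sample.int(length(n_slices_choices), n,
                                          replace = TRUE,
                                          prob = n_slices_weights /
                                            sum(n_slices_weights))]
  jit <- data.frame(body = runif(n, 0.92, 1.08),
                    sat = runif(n, 0.85, 1.15),
                    sm = runif(n, 0.90, 1.10),
                    vat = runif(n, 0.85, 1.15),
                    amp_mag_body = runif(n, 0.5, 1.5),
                    amp_mag_sat = runif(n, 0.5, 1.5),
                    amp_mag_vat = runif(n, 0.5, 1.5),
                    sgn_body = sample(c(-1, 1), n, replace = TRUE),
                    sgn_sat = sample(c(-1, 1), n, replace = TRUE),
                    sgn_vat = sample(c(-1, 1), n, replace = TRUE),
                    age = round(runif(n, 35, 85)))
  defaults <- formals(phantom_params)
  base_val <- function(name) if (!is.null(base[[name]])) base[[name]] else
    eval(defaults[[name]])
  out <- vector("list", n)
  for (i in seq_len(n)) {
    eff <- sex_effects[[sexes[i]]]
    args <- base
    args$seed <- seeds[i]
    args$patient_id <- sprintf("P%03d", i)
    args$sex <- sexes[i]
    args$age_years <- jit$age[i]
    args$n_slices <- n_slices[i]
    args$body_a <- base_val("body_a") * eff$body * jit$body[i]
    args$body_b <- base_val("body_b") * eff$body * jit$body[i]
    args$sat_thick <- base_val("sat_thick") * eff$sat * jit$sat[i]
    args$sm_thick <- base_val("sm_thick") * eff$sm * jit$sm[i]
    args$vat_frac <- min(max(base_val("vat_frac") * eff$vat_frac * jit$vat[i],
                             0.05), 0.90)
    args$body_amp <- base_val("body_amp") * eff$body_amp *
      jit$amp_mag_body[i] * jit$sgn_body[i]
    args$sat_amp <- base_val("sat_amp") * eff$sat_amp *
      jit$amp_mag_sat[i] * jit$sgn_sat[i]
    args$vat_amp <- base_val("vat_amp") * eff$vat_amp *
      jit$amp_mag_vat[i] * jit$sgn_vat[i]
    out[[i]] <- generate_phantom_study(do.call(phantom_params, args),
                                       render = render)
  }
  out
}

#' Pool a cohort's ground-truth measures and patient table
#'
#' @param cohort List from \code{\link{generate_cohort}}.
#' @return List with \code{measures} (pooled per-slice truth measures) and
#'   \code{patients} (patient_id, sex, age_years).
#' @export
cohort_truth_measures <- function(cohort) {
  measures <- do.call(rbind, lapply(cohort, truth_measures))
  patients <- do.call(rbind, lapply(cohort, function(ph) data.frame(
    patient_id = ph$truth$params$patient_id,
    sex = ph$truth$params$sex,
    age_years = ph$truth$params$age_years,
    stringsAsFactors = FALSE)))
  list(measures = measures, patients = patients)
}

#' Write a study as a DICOM series plus manifest rows
#'
#' One file per slice (\code{<patient>_<index>.dcm}); manifest rows are
#' appended to \code{manifest.tsv} in the target directory.
#'
#' @param study A \code{patient_study}.
#' @param dir Writable output directory (created if missing).
#' @return Character vector of file paths written.
#' @export
write_dicom_series <- function(study, dir) {
  stopifnot(inherits(study, "patient_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir) || file.access(dir, 2L) != 0L)
    stop("I/O error: directory not writable: ", dir, call. = FALSE)
  files <- character(length(study$slices))
  for (i in seq_along(study$slices)) {
    fn <- sprintf("%s_%03d.dcm", study$patient_id, i)
    write_dicom_slice(study$slices[[i]], file.path(dir, fn),
                      instance_number = i, sex = study$sex)
    files[i] <- fn
  }
  man_path <- file.path(dir, "manifest.tsv")
  rows <- data.frame(patient_id = study$patient_id, sex = study$sex,
                     age_years = study$age_years, file = files,
                     is_mid = seq_along(files) == study$mid_index,
                     stringsAsFactors = FALSE)
  if (file.exists(man_path)) {
    old <- read_manifest(man_path)
    rows <- rbind(old[old$patient_id != study$patient_id, , drop = FALSE],
                  rows)
  }
  write_manifest(rows, man_path)
  file.path(dir, files)
}
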