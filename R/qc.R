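# Automated quality-control flags mirroring the study exclusion criteria:
# subcutaneous fat or muscle cut off at the image border, excessive image
# noise, and major (metal-like) artefacts.

#' Quality-control check of a patient study
#'
#' Flags per study: \code{sat_cutoff} if any SAT-labelled pixel touches the
#' image border (fat extending outside the field of view), \code{muscle_cutoff}
#' likewise for SM, \code{low_quality} if a robust noise estimate (1.4826 x
#' median absolute deviation of HU in a central body-interior window) exceeds
#' \code{noise_sd_max}, and \code{major_artefact} if any |HU| inside the body
#' exceeds \code{artefact_hu}. An empty flag set means the study passes
#' inclusion.
#'
#' @param study A \code{patient_study}.
#' @param masks List of label masks aligned to \code{study$slices}.
#' @param noise_sd_max Robust noise SD threshold in HU (default 25).
#' @param artefact_hu Absolute HU bound for artefact detection (default 3000).
#' @param window Half-width in pixels of the central noise-estimation window
#'   (default 32, i.e. a 64 x 64 window).
#'
#' @return List of class \code{qc_report}: \code{patient_id}, \code{flags}
#'   (character vector, possibly empty), \code{pass}, and \code{per_slice}
#'   data frame with flag provenance.
#' @export
qc_study <- function(study, masks, noise_sd_max = 25, artefact_hu = 3000,
                     window = 32L) {
  stopifnot(inherits(study, "patient_study"))
  if (length(masks) != length(study$slices))
    stop("alignment error: one mask per slice required", call. = FALSE)
  rows <- list()
  for (i in seq_along(study$slices)) {
    s <- study$slices[[i]]
    lab <- masks[[i]]
    if (!identical(dim(lab), dim(s$hu_image)))
      stop("alignment error: mask/slice shape mismatch at slice ", i,
           call. = FALSE)
    nr <- nrow(lab); nc <- ncol(lab)
    border <- rbind(lab[1, , drop = FALSE], lab[nr, , drop = FALSE],
                    t(lab[, 1, drop = FALSE]), t(lab[, nc, drop = FALSE]))
    add <- function(flag, detail)
      rows[[length(rows) + 1L]] <<- data.frame(
        slice_index = i, flag = flag, detail = detail,
        stringsAsFactors = FALSE)
    if (any(border == LABEL_LEVELS[["SAT"]]))
      add("sat_cutoff", "SAT touches image border")
    if (any(border == LABEL_LEVELS[["SM"]]))
      add("muscle_cutoff", "SM touches image border")
    body <- tryCatch(body_mask(s$hu_image), error = function(e) NULL)
    ctr <- c(round(nr / 2), round(nc / 2))
    ri <- max(1L, ctr[1] - window):min(nr, ctr[1] + window - 1L)
    ci <- max(1L, ctr[2] - window):min(nc, ctr[2] + window - 1L)
    win <- s$hu_image[ri, ci]
    noise <- stats::mad(win)
    if (is.finite(noise) && noise > noise_sd_max)
      add("low_quality", sprintf("robust noise SD %.1f HU > %.1f", noise,
                                 noise_sd_max))
    if (!is.null(body) && any(abs(s$hu_image[body]) > artefact_hu))
      add("major_artefact",
          sprintf("|HU| > %g inside body (max %g)", artefact_hu,
                  max(abs(s$hu_image[body]))))
  }
  per_slice <- if (length(rows)) do.call(rbind, rows) else
    data.frame(slice_index = integer(), flag = character(),
               detail = character(), stringsAsFactors = FALSE)
  flags <- sort(unique(per_slice$flag))
  structure(list(patient_id = study$patient_id, flags = flags,
                 pass = length(flags) == 0L, per_slice = per_slice),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s: %s\n", x$patient_id,
              if (x$pass) "PASS" else paste(x$flags, collapse = ", ")))
  invisible(x)
}
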