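# HU-threshold segmentation with morphological visceral/subcutaneous
# compartment separation. Connectivity conventions: 8-neighbour for connected
# components, 4-neighbour for hole filling.

#' Alberta-protocol tissue HU thresholds
#'
#' Inclusive Hounsfield-unit ranges used by the SliceOmatic/Alberta grading
#' convention: skeletal muscle (SM) -29..150 HU, visceral adipose tissue (VAT)
#' -150..-50 HU, subcutaneous adipose tissue (SAT) -190..-30 HU. Note the two
#' fat ranges overlap; VAT and SAT are disambiguated spatially by
#' \code{\link{segment_composition}}.
#'
#' @return Named list of length-2 numeric vectors \code{c(low, high)}.
#' @export
alberta_thresholds <- function() {
  list(SM = c(-29, 150), VAT = c(-150, -50), SAT = c(-190, -30))
}

validate_thresholds <- function(thresholds) {
  if (!all(TISSUES %in% names(thresholds)))
    stop("thresholds must contain SM, VAT and SAT entries", call. = FALSE)
  for (t in TISSUES) {
    b <- thresholds[[t]]
    if (length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2])
      stop("threshold bounds for ", t, " must satisfy low < high",
           call. = FALSE)
  }
  invisible(thresholds)
}

disc_brush <- function(radius) EBImage::makeBrush(2L * as.integer(radius) + 1L,
                                                  shape = "disc")

morph_close <- function(mask, radius) {
  if (radius <= 0) return(mask)
  m <- EBImage::closing(mask * 1, disc_brush(radius))
  matrix(m > 0.5, nrow = nrow(mask))
}

largest_component <- function(mask) {
  lab <- .label_components(mask, 8L)
  if (max(lab) == 0L) return(NULL)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

remove_small_objects <- function(mask, min_px) {
  if (min_px <= 1L || !any(mask)) return(mask)
  lab <- .label_components(mask, 8L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_px)
  mask & matrix(lab %in% keep, nrow = nrow(mask))
}

#' Extract the body mask from an HU image
#'
#' Pixels with HU strictly above \code{air_hu} are morphologically closed; the
#' largest 8-connected component is kept and its interior holes (e.g. bowel
#' gas) are filled with 4-connected flood fill.
#'
#' @param hu_image Numeric HU matrix.
#' @param air_hu HU threshold separating body tissue from air (default -190,
#'   the lower bound of the SAT range).
#' @param closing_radius Disc radius in pixels for morphological closing.
#'
#' @return Logical matrix, TRUE inside the body.
#' @export
body_mask <- function(hu_image, air_hu = -190, closing_radius = 5L) {
  if (!is.matrix(hu_image) || !is.numeric(hu_image))
    stop("hu_image must be a numeric matrix", call. = FALSE)
  cand <- hu_image > air_hu
  if (!any(cand))
    stop("no body found: image contains no pixels above ", air_hu, " HU",
         call. = FALSE)
  cand <- morph_close(cand, closing_radius)
  comp <- largest_component(cand)
  if (is.null(comp))
    stop("no body found in image", call. = FALSE)
  .fill_holes(comp)
}

#' Threshold one tissue's HU range
#'
#' @param hu_image Numeric HU matrix.
#' @param thresholds Threshold set, see \code{\link{alberta_thresholds}}.
#' @param tissue One of "SM", "VAT", "SAT".
#'
#' @return Logical matrix, TRUE where \code{low <= HU <= high} (inclusive).
#' @export
threshold_tissue <- function(hu_image, thresholds = alberta_thresholds(),
                             tissue) {
  if (length(tissue) != 1L || !tissue %in% TISSUES)
    stop("invalid argument: tissue must be one of ",
         paste(TISSUES, collapse = ", "), call. = FALSE)
  validate_thresholds(thresholds)
  b <- thresholds[[tissue]]
  hu_image >= b[1] & hu_image <= b[2]
}

#' Segment skeletal muscle and adipose compartments of one slice
#'
#' Threshold-plus-morphology segmentation: SM is the muscle-range pixels
#' inside the body after small-object removal; the outer muscle contour is the
#' hole-filled morphological closing of SM; VAT is the VAT-range pixels inside
#' that contour; SAT is the SAT-range pixels between the contour and the body
#' boundary. The two fat HU ranges overlap, so compartment geometry (not HU)
#' decides VAT vs SAT.
#'
#' @param hu_image Numeric HU matrix containing a body.
#' @param thresholds Tissue HU bounds (default Alberta protocol).
#' @param closing_radius Disc radius (px) for morphological closing of the
#'   muscle wall (default 5).
#' @param min_object_px Minimum connected-component size kept in the SM mask
#'   (default 20); removes isolated muscle-range speckle such as small bowel
#'   content.
#' @param air_hu Body/air HU boundary passed to \code{\link{body_mask}}.
#'
#' @return Integer label matrix (see \code{\link{tissue_labels}}) with
#'   attribute \code{"thresholds"}.
#' @export
segment_composition <- function(hu_image, thresholds = alberta_thresholds(),
                                closing_radius = 5L, min_object_px = 20L,
                                air_hu = -190) {
  validate_thresholds(thresholds)
  body <- body_mask(hu_image, air_hu = air_hu, closing_radius = closing_radius)
  sm <- threshold_tissue(hu_image, thresholds, "SM") & body
  sm <- remove_small_objects(sm, min_object_px)
  contour <- .fill_holes(morph_close(sm, closing_radius))
  vat <- threshold_tissue(hu_image, thresholds, "VAT") & contour & !sm
  sat <- threshold_tissue(hu_image, thresholds, "SAT") & body & !contour
  labels <- matrix(LABEL_LEVELS[["background"]], nrow(hu_image), ncol(hu_image))
  labels[sm] <- LABEL_LEVELS[["SM"]]
  labels[vat] <- LABEL_LEVELS[["VAT"]]
  labels[sat] <- LABEL_LEVELS[["SAT"]]
  attr(labels, "thresholds") <- thresholds
  labels
}

#' Sorensen-Dice overlap coefficient
#'
#' \code{2 |A intersect B| / (|A| + |B|)}; defined as 1 when both masks are
#' empty.
#'
#' @param mask_a,mask_b Logical matrices of identical shape.
#' @return Number in [0, 1].
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("alignment error: masks have different shapes", call. = FALSE)
  a <- sum(mask_a); b <- sum(mask_b)
  if (a + b == 0) return(1)
  2 * sum(mask_a & mask_b) / (a + b)
}

#' Persist or load a label mask as PNG with a JSON sidecar
#'
#' Labels 0..3 are stored as grey levels 0, 85, 170, 255 in a single-channel
#' PNG; the sidecar records the source slice identifier and threshold set.
#'
#' @param labels Integer label matrix.
#' @param path PNG output path (sidecar gets extension .json).
#' @param slice_id Identifier of the source slice.
#' @param thresholds Threshold set used to produce the mask.
#' @return \code{path}, invisibly.
#' @export
write_mask_png <- function(labels, path, slice_id = "",
                           thresholds = attr(labels, "thresholds")) {
  png::writePNG(matrix(as.numeric(labels) * 85 / 255, nrow(labels)), path)
  sidecar <- sub("\\.png$", ".json", path)
  jsonlite::write_json(
    list(slice_id = slice_id, levels = as.list(LABEL_LEVELS),
         thresholds = thresholds),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  labels <- matrix(as.integer(round(img * 255 / 85)), nrow(img))
  sidecar <- sub("\\.png$", ".json", path)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$thresholds))
      attr(labels, "thresholds") <- lapply(meta$thresholds, as.numeric)
  }
  labels
}
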