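#' Analysis configuration
#'
#' Tunable parameters of the per-eye pipeline.
#'
#' @param vessel_threshold intensity threshold for the C-scan: a pixel
#'   is vessel iff its intensity is `<= vessel_threshold` when vessels
#'   are dark (default 60, the value found most effective for choroidal
#'   vascular selection).
#' @param mark_threshold intensity above which a pixel on the marked IR
#'   image counts as part of a paint mark (default 200; marks are
#'   bright by default).
#' @param min_mark_area smallest connected mark area (pixels) that
#'   yields a lesion point, default 1.
#' @param vessel_is_dark are vessels hyporeflective (low intensity) on
#'   the C-scan? Default `TRUE`.
#' @param marks_are_bright are paint marks brighter than the IR
#'   background? Default `TRUE`; set `FALSE` for dark marks, in which
#'   case pixels `<= mark_threshold` count as mark.
#' @param connectivity pixel connectivity for mark components, 4 or 8
#'   (default 8).
#' @param min_lesions per-eye inclusion rule: eyes with fewer included
#'   lesions are skipped at the cohort level (default 50).
#' @return An `analysis_config` object.
#' @export
analysis_config <- function(vessel_threshold = 60,
                            mark_threshold = 200,
                            min_mark_area = 1,
                            vessel_is_dark = TRUE,
                            marks_are_bright = TRUE,
                            connectivity = 8,
                            min_lesions = 50) {
  stopifnot(vessel_threshold >= 0, vessel_threshold <= 255,
            mark_threshold >= 0, mark_threshold <= 255,
            min_mark_area >= 1, connectivity %in% c(4, 8),
            is.logical(vessel_is_dark), is.logical(marks_are_bright),
            min_lesions >= 0)
  structure(
    list(vessel_threshold = vessel_threshold,
         mark_threshold = mark_threshold,
         min_mark_area = as.integer(min_mark_area),
         vessel_is_dark = isTRUE(vessel_is_dark),
         marks_are_bright = isTRUE(marks_are_bright),
         connectivity = as.integer(connectivity),
         min_lesions = as.integer(min_lesions)),
    class = "analysis_config"
  )
}

#' Binarize a C-scan into a vessel/stroma map
#'
#' Thresholds the en face C-scan: with dark vessels (the default), a
#' pixel is vessel iff intensity `<= vessel_threshold`; with bright
#' vessels, iff intensity `>= vessel_threshold`. The inclusive rule is
#' deliberate and unit-tested at the boundary.
#'
#' @param cscan a [grayscale_image].
#' @param config an [analysis_config()].
#' @return A [binary_mask] with `semantics = "vessel"`.
#' @export
binarize_vessels <- function(cscan, config = analysis_config()) {
  stopifnot(inherits(cscan, "grayscale_image"),
            inherits(config, "analysis_config"))
  fg <- if (config$vessel_is_dark) {
    cscan$intensities <= config$vessel_threshold
  } else {
    cscan$intensities >= config$vessel_threshold
  }
  if (all(fg) || !any(fg)) {
    message(sprintf("degenerate vessel mask: %s pixels are vessel",
                    if (all(fg)) "all" else "no"))
  }
  binary_mask(fg, semantics = "vessel")
}

#' Build the analysis region
#'
#' The analysis region is the full frame minus the exclusion mask
#' (areas corresponding to retinal-vessel artifacts on the C-scan).
#' Lesions and control points falling outside it are excluded.
#'
#' @param image a [grayscale_image] defining the frame.
#' @param exclusion optional [binary_mask] with `semantics =
#'   "exclusion"`; `NULL` means nothing is excluded.
#' @return A [binary_mask] with `semantics = "analysis_region"`.
#' @export
build_analysis_region <- function(image, exclusion = NULL) {
  stopifnot(inherits(image, "grayscale_image"))
  fg <- matrix(TRUE, nrow(image$intensities), ncol(image$intensities))
  if (!is.null(exclusion)) {
    stopifnot(inherits(exclusion, "binary_mask"))
    check_same_dim(image$intensities, exclusion$foreground,
                   "image and exclusion mask")
    fg <- fg & !exclusion$foreground
  }
  if (!any(fg)) warning("analysis region is empty")
  binary_mask(fg, semantics = "analysis_region")
}

#' Extract single-point lesion centers from a marked IR image
#'
#' Thresholds the marked image to isolate the paint marks, labels
#' connected components, and returns one point per component of area
#' `>= min_mark_area`: the component centroid rounded to the nearest
#' pixel (round half away from zero). This is the stable analogue of
#' an intensity-maxima single-point output for flat paintbrush marks.
#'
#' @param marked a [grayscale_image] carrying the paint marks.
#' @param config an [analysis_config()] (uses `mark_threshold`,
#'   `marks_are_bright`, `min_mark_area`, `connectivity`).
#' @return A [point_map] with `label = "observed"`, one point per mark.
#' @export
extract_lesion_points <- function(marked, config = analysis_config()) {
  stopifnot(inherits(marked, "grayscale_image"),
            inherits(config, "analysis_config"))
  fg <- if (config$marks_are_bright) {
    marked$intensities >= config$mark_threshold
  } else {
    marked$intensities <= config$mark_threshold
  }
  h <- nrow(fg)
  w <- ncol(fg)
  if (!any(fg)) {
    warning("no mark components found; returning empty point map")
    return(point_map(data.frame(row = integer(0), col = integer(0)),
                     h, w, label = "observed"))
  }
  lab <- cpp_label_components(fg, config$connectivity)
  idx <- which(lab > 0L)
  labs <- lab[idx]
  rows0 <- (idx - 1L) %% h        # 0-based row
  cols0 <- (idx - 1L) %/% h       # 0-based col
  area <- tabulate(labs)
  keep <- which(area >= config$min_mark_area)
  cr <- vapply(split(rows0, labs), mean, numeric(1))[keep]
  cc <- vapply(split(cols0, labs), mean, numeric(1))[keep]
  # round half away from zero (coords are nonnegative, so floor(x+0.5)),
  # then clamp inside the frame
  pr <- pmin(pmax(floor(cr + 0.5), 0), h - 1L)
  pc <- pmin(pmax(floor(cc + 0.5), 0), w - 1L)
  pts <- unique(data.frame(row = as.integer(pr), col = as.integer(pc)))
  point_map(pts, h, w, label = "observed")
}

#' Filter points to the analysis region
#'
#' @param points a [point_map].
#' @param region a [binary_mask] with `semantics = "analysis_region"`.
#' @return A list with `kept` (a [point_map]) and `n_excluded` (count);
#'   `n_points(kept) + n_excluded == n_points(points)` always.
#' @export
filter_points_by_region <- function(points, region) {
  stopifnot(inherits(points, "point_map"), inherits(region, "binary_mask"))
  if (points$frame_height != nrow(region$foreground) ||
      points$frame_width != ncol(region$foreground)) {
    stop("dimension mismatch between points frame and region")
  }
  inside <- region$foreground[cbind(points$points$row + 1L,
                                    points$points$col + 1L)]
  if (nrow(points$points) == 0L) inside <- logical(0)
  kept <- point_map(points$points[inside, , drop = FALSE],
                    points$frame_height, points$frame_width,
                    label = points$label)
  list(kept = kept, n_excluded = sum(!inside))
}
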