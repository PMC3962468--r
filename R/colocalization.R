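#' Classify points against the vessel mask
#'
#' A point counts as vessel iff its pixel is vessel foreground — the
#' direct equivalent of multiplying a value-1 lesion raster with the
#' 255/0 vessel map and counting 255s in the histogram (that product
#' route is available as [classify_points_multiply()] and the two must
#' agree exactly).
#'
#' @param points a [point_map], already filtered to the analysis
#'   region.
#' @param vessels a [binary_mask] with `semantics = "vessel"`.
#' @param field optional `distance_field`; computed from `vessels` when
#'   `NULL` and per-point proximity classes are wanted.
#' @return A list: `n_vessel`, `n_stroma`, and `per_point` (factor of
#'   proximity classes; `NULL` when the mask has no vessel pixel).
#' @export
classify_points <- function(points, vessels, field = NULL) {
  stopifnot(inherits(points, "point_map"), inherits(vessels, "binary_mask"))
  if (points$frame_height != nrow(vessels$foreground) ||
      points$frame_width != ncol(vessels$foreground)) {
    stop("dimension mismatch between points frame and vessel mask")
  }
  if (nrow(points$points) == 0L) {
    return(list(n_vessel = 0L, n_stroma = 0L,
                per_point = factor(character(0), levels = PROXIMITY_LEVELS)))
  }
  on_vessel <- vessels$foreground[cbind(points$points$row + 1L,
                                        points$points$col + 1L)]
  if (is.null(field) && any(vessels$foreground)) {
    field <- compute_distance_field(vessels)
  }
  per_point <- if (is.null(field)) NULL else {
    classify_proximity(points, field, vessels)
  }
  list(n_vessel = sum(on_vessel), n_stroma = sum(!on_vessel),
       per_point = per_point)
}

#' Product-then-histogram vessel count (reference route)
#'
#' Builds the value-1 single-pixel lesion raster, multiplies it by the
#' 255/0 vessel raster, and counts pixels equal to 255 — the histogram
#' route. Used as a cross-check against [classify_points()].
#'
#' @inheritParams classify_points
#' @return Number of points over vessel foreground.
#' @export
classify_points_multiply <- function(points, vessels) {
  stopifnot(inherits(points, "point_map"), inherits(vessels, "binary_mask"))
  h <- nrow(vessels$foreground)
  w <- ncol(vessels$foreground)
  lesion <- matrix(0L, h, w)
  if (nrow(points$points) > 0L) {
    lesion[cbind(points$points$row + 1L, points$points$col + 1L)] <- 1L
  }
  vmap <- matrix(0L, h, w)
  vmap[vessels$foreground] <- 255L
  prod <- lesion * vmap
  sum(tabulate(prod + 1L, nbins = 256L)[256L]) # histogram count at 255
}

# Summarize one classified point set into counts / percentages.
summarize_point_set <- function(cls) {
  n <- length(cls)
  counts <- table(cls)
  n_vessel <- as.integer(counts[["over_vessel"]])
  n_stroma <- n - n_vessel
  bins <- as.integer(counts[c("near_1_3", "mid_4_6", "far_ge7")])
  names(bins) <- c("near_1_3", "mid_4_6", "far_ge7")
  list(
    n = n,
    n_vessel = n_vessel,
    n_stroma = n_stroma,
    pct_vessel = if (n > 0) 100 * n_vessel / n else NA_real_,
    pct_stroma = if (n > 0) 100 * n_stroma / n else NA_real_,
    stroma_bins = list(
      counts = bins,
      pct = if (n_stroma > 0) 100 * bins / n_stroma else
        stats::setNames(rep(NA_real_, 3), names(bins))
    )
  )
}

#' Analyze a single eye
#'
#' Runs the full per-eye chain: extract lesion points from the marked
#' IR image, build the analysis region, drop lesions in excluded
#' areas, binarize the C-scan into a vessel map (vessels inside
#' excluded areas are removed), classify every lesion as over-vessel
#' or stroma, bin stroma lesions by distance, then generate and
#' classify a count-matched uniform control set. Deterministic given
#' `seed`.
#'
#' @param eye_id identifier echoed into the result.
#' @param marked marked IR [grayscale_image].
#' @param cscan en face C-scan [grayscale_image], co-registered and
#'   same size as `marked`.
#' @param exclusion optional retinal-vessel [binary_mask]
#'   (`semantics = "exclusion"`).
#' @param config an [analysis_config()].
#' @param seed integer seed for the control draw.
#' @return An `eye_result` object (see Details).
#' @details The result fields: `n_marked` (marks found), `n_excluded`
#'   (marks inside excluded areas), `n_included`, `observed` and
#'   `control` summaries (each with `n_vessel`, `n_stroma`,
#'   `pct_vessel`, `pct_stroma`, `stroma_bins$counts`,
#'   `stroma_bins$pct`), and `vessel_area_fraction` (vessel share of
#'   the analysis region — the expected on-vessel fraction of a
#'   uniform point set).
#' @export
analyze_eye <- function(eye_id, marked, cscan, exclusion = NULL,
                        config = analysis_config(), seed = 1L) {
  stopifnot(inherits(marked, "grayscale_image"),
            inherits(cscan, "grayscale_image"))
  check_same_dim(marked$intensities, cscan$intensities,
                 "marked IR and C-scan")
  region <- build_analysis_region(cscan, exclusion)
  if (!any(region$foreground)) {
    stop(sprintf("eye %s: analysis region is empty", eye_id))
  }
  pts <- extract_lesion_points(marked, config)
  n_marked <- n_points(pts)
  filt <- filter_points_by_region(pts, region)
  if (n_points(filt$kept) == 0L) {
    stop(sprintf("eye %s: no lesion points inside the analysis region",
                 eye_id))
  }
  vessels <- binarize_vessels(cscan, config)
  # excluded areas carry no vessel reference
  vessels$foreground <- vessels$foreground & region$foreground
  if (!any(vessels$foreground)) {
    stop(sprintf("eye %s: no vessel pixels after exclusion", eye_id))
  }
  field <- compute_distance_field(vessels)
  obs_cls <- classify_proximity(filt$kept, field, vessels)
  controls <- generate_control_points(n_points(filt$kept), region, seed)
  ctl_cls <- classify_proximity(controls, field, vessels)
  structure(
    list(
      eye_id = eye_id,
      seed = as.integer(seed),
      n_marked = n_marked,
      n_excluded = filt$n_excluded,
      n_included = n_points(filt$kept),
      observed = summarize_point_set(obs_cls),
      control = summarize_point_set(ctl_cls),
      vessel_area_fraction =
        sum(vessels$foreground) / sum(region$foreground),
      pixel_size_um = cscan$pixel_size_um
    ),
    class = "eye_result"
  )
}

#' @export
print.eye_result <- function(x, ...) {
  cat(sprintf("<eye_result %s: %d marked, %d excluded, %d included>\n",
              x$eye_id, x$n_marked, x$n_excluded, x$n_included))
  cat(sprintf("  observed: %.1f%% over vessels; stroma bins %s%%\n",
              x$observed$pct_vessel,
              paste(sprintf("%.1f", x$observed$stroma_bins$pct),
                    collapse = " / ")))
  cat(sprintf("  control : %.1f%% over vessels; stroma bins %s%%\n",
              x$control$pct_vessel,
              paste(sprintf("%.1f", x$control$stroma_bins$pct),
                    collapse = " / ")))
  cat(sprintf("  vessel area fraction %.3f\n", x$vessel_area_fraction))
  invisible(x)
}

#' Serialize an eye result to JSON
#'
#' Raw (unrounded) values are written; display rounding is one decimal
#' place elsewhere.
#'
#' @param result an `eye_result`.
#' @param path output JSON path.
#' @export
write_eye_result <- function(result, path) {
  stopifnot(inherits(result, "eye_result"))
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(NULL)
}
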