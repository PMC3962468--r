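#' Count-matched uniform random control points
#'
#' The chance baseline: `n_points` distinct pixels sampled uniformly
#' without replacement from the analysis region, matching the number of
#' observed lesions on the same eye. Controls never fall in excluded
#' areas, so the observed-vs-control comparison is like-for-like.
#'
#' @param n_points number of control points (equal to the eye's
#'   included lesion count).
#' @param region a [binary_mask] with `semantics = "analysis_region"`.
#' @param seed integer seed; the draw is reproducible from it.
#' @param allow_collisions if `TRUE`, sample with replacement (several
#'   controls may share a pixel; the returned map then holds the unique
#'   pixels and this mode is only for sensitivity checks via
#'   [classify_points()] on raw coordinates). Default `FALSE`.
#' @return A [point_map] with `label = "control"`.
#' @export
generate_control_points <- function(n_points, region, seed,
                                    allow_collisions = FALSE) {
  stopifnot(inherits(region, "binary_mask"), n_points >= 0)
  h <- nrow(region$foreground)
  idx <- which(region$foreground)
  if (!allow_collisions && n_points > length(idx)) {
    stop(sprintf("capacity error: %d points requested from a %d-pixel region",
                 n_points, length(idx)))
  }
  if (length(idx) == 0L && n_points > 0L) {
    stop("analysis region is empty")
  }
  sel <- with_seed(seed, {
    if (allow_collisions) {
      unique(sample(idx, n_points, replace = TRUE))
    } else {
      sample(idx, n_points, replace = FALSE)
    }
  })
  pts <- data.frame(row = (sel - 1L) %% h, col = (sel - 1L) %/% h)
  point_map(pts, h, ncol(region$foreground), label = "control")
}
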