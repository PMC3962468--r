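#' OCT macular cube geometry
#'
#' Describes a macular cube volume-scan protocol and the geometry of
#' its en face export, so pixel measurements can be converted to
#' microns. Defaults describe a 512x128 cube over a 6 mm square grid
#' at 2 mm depth with 1024 samples per A-scan, exported at 600x600
#' pixels.
#'
#' @param physical_width_um,physical_height_um en face field size in
#'   microns (default 6000 each).
#' @param physical_depth_um axial depth in microns (default 2000).
#' @param a_scans_per_b A-scans per B-scan (default 512).
#' @param b_scans B-scans per volume (default 128).
#' @param samples_per_a_scan axial samples per A-scan (default 1024).
#' @param export_width_px,export_height_px exported C-scan raster size
#'   (default 600x600).
#' @return A `cube_geometry` object.
#' @export
cube_geometry <- function(physical_width_um = 6000,
                          physical_height_um = 6000,
                          physical_depth_um = 2000,
                          a_scans_per_b = 512,
                          b_scans = 128,
                          samples_per_a_scan = 1024,
                          export_width_px = 600,
                          export_height_px = 600) {
  vals <- c(physical_width_um, physical_height_um, physical_depth_um,
            a_scans_per_b, b_scans, samples_per_a_scan,
            export_width_px, export_height_px)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all geometry parameters must be positive")
  }
  structure(
    list(physical_width_um = physical_width_um,
         physical_height_um = physical_height_um,
         physical_depth_um = physical_depth_um,
         a_scans_per_b = a_scans_per_b,
         b_scans = b_scans,
         samples_per_a_scan = samples_per_a_scan,
         export_width_px = export_width_px,
         export_height_px = export_height_px),
    class = "cube_geometry"
  )
}

#' Native acquisition pixel spacing
#'
#' Spacing between acquisition samples: horizontal = field width /
#' A-scans per B-scan (6000/512 = 11.7 um for the default protocol),
#' vertical = field height / B-scans (6000/128 = 46.9 um), axial =
#' depth / samples per A-scan (2000/1024, approximately 2 um). Raw
#' values are returned; round to one decimal for display.
#'
#' @param geom a [cube_geometry()].
#' @return Named list: `horizontal_um`, `vertical_um`, `axial_um`.
#' @export
native_pixel_spacing <- function(geom) {
  stopifnot(inherits(geom, "cube_geometry"))
  list(horizontal_um = geom$physical_width_um / geom$a_scans_per_b,
       vertical_um = geom$physical_height_um / geom$b_scans,
       axial_um = geom$physical_depth_um / geom$samples_per_a_scan)
}

#' Microns per exported C-scan pixel
#'
#' Field width divided by the export raster width: a 6 mm cube
#' exported at 600 pixels gives 10 microns per pixel, regardless of
#' the acquisition protocol (200x200 and 512x128 cubes over the same
#' field export identically).
#'
#' @param geom a [cube_geometry()].
#' @return Microns per pixel (scalar).
#' @export
export_pixel_size <- function(geom) {
  stopifnot(inherits(geom, "cube_geometry"))
  geom$physical_width_um / geom$export_width_px
}

#' Convert a pixel distance to microns
#'
#' @param d distance in pixels, nonnegative.
#' @param scale microns per pixel (default 10).
#' @return Distance in microns.
#' @export
pixels_to_microns <- function(d, scale = 10) {
  if (any(d < 0)) stop("distance must be nonnegative")
  if (scale <= 0) stop("scale must be positive")
  d * scale
}

#' Convert a micron distance to pixels
#'
#' Exact inverse of [pixels_to_microns()].
#'
#' @param um distance in microns, nonnegative.
#' @param scale microns per pixel (default 10).
#' @return Distance in pixels.
#' @export
microns_to_pixels <- function(um, scale = 10) {
  if (any(um < 0)) stop("distance must be nonnegative")
  if (scale <= 0) stop("scale must be positive")
  um / scale
}
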