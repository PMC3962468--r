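#' Grayscale image container
#'
#' An 8-bit single-channel raster with an isotropic physical pixel
#' size. Intensities are stored as an integer matrix (rows = image
#' rows, row 1 of the matrix is the top image row). All coordinates in
#' this package are 0-based `(row, col)` with the origin at the
#' top-left pixel.
#'
#' @param intensities integer matrix with values in `[0, 255]`.
#' @param pixel_size_um microns per pixel (isotropic), default 10 (a
#'   6 mm field exported at 600 pixels).
#' @return A `grayscale_image` object.
#' @export
grayscale_image <- function(intensities, pixel_size_um = 10) {
  if (!is.matrix(intensities)) stop("intensities must be a matrix")
  if (nrow(intensities) < 1L || ncol(intensities) < 1L) {
    stop("image must have positive dimensions")
  }
  if (anyNA(intensities)) stop("intensities contain NA")
  if (any(intensities < 0 | intensities > 255)) {
    stop("intensities must lie in [0, 255]")
  }
  if (any(intensities != round(intensities))) {
    stop("intensities must be integers")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0) {
    stop("pixel_size_um must be a positive scalar")
  }
  storage.mode(intensities) <- "integer"
  structure(
    list(intensities = intensities, pixel_size_um = as.numeric(pixel_size_um)),
    class = "grayscale_image"
  )
}

#' @export
dim.grayscale_image <- function(x) dim(x$intensities)

#' @export
print.grayscale_image <- function(x, ...) {
  cat(sprintf("<grayscale_image %d x %d, %.3g um/px, range [%d, %d]>\n",
              nrow(x$intensities), ncol(x$intensities), x$pixel_size_um,
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Binary mask container
#'
#' A per-pixel boolean map with explicit foreground semantics: what
#' `TRUE` means. `"vessel"` marks choroidal vessel pixels, `"exclusion"`
#' marks retinal-vessel artifact regions to drop, `"analysis_region"`
#' marks pixels eligible for analysis.
#'
#' @param foreground logical matrix.
#' @param semantics one of `"vessel"`, `"exclusion"`, `"analysis_region"`.
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(foreground,
                        semantics = c("vessel", "exclusion", "analysis_region")) {
  semantics <- match.arg(semantics)
  if (!is.matrix(foreground) || !is.logical(foreground)) {
    stop("foreground must be a logical matrix")
  }
  if (anyNA(foreground)) stop("foreground contains NA")
  if (nrow(foreground) < 1L || ncol(foreground) < 1L) {
    stop("mask must have positive dimensions")
  }
  structure(list(foreground = foreground, semantics = semantics),
            class = "binary_mask")
}

#' @export
dim.binary_mask <- function(x) dim(x$foreground)

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask [%s] %d x %d, %d foreground px (%.1f%%)>\n",
              x$semantics, nrow(x$foreground), ncol(x$foreground),
              sum(x$foreground), 100 * mean(x$foreground)))
  invisible(x)
}

#' Lesion / control point set tied to an image frame
#'
#' Single-pixel point coordinates, 0-based `(row, col)`, top-left
#' origin. Duplicate coordinates and out-of-frame points are rejected.
#'
#' @param points data.frame (or matrix) with integer columns `row`,
#'   `col`; may have zero rows.
#' @param frame_height,frame_width frame dimensions in pixels.
#' @param label `"observed"` or `"control"`.
#' @return A `point_map` object.
#' @export
point_map <- function(points, frame_height, frame_width,
                      label = c("observed", "control")) {
  label <- match.arg(label)
  points <- as.data.frame(points)
  if (nrow(points) == 0L) {
    points <- data.frame(row = integer(0), col = integer(0))
  }
  if (!all(c("row", "col") %in% names(points))) {
    stop("points must have columns 'row' and 'col'")
  }
  points <- data.frame(row = as.integer(points$row),
                       col = as.integer(points$col))
  if (anyNA(points)) stop("point coordinates contain NA")
  if (any(points$row < 0L | points$row >= frame_height |
          points$col < 0L | points$col >= frame_width)) {
    stop("points must lie inside the frame (0-based row/col)")
  }
  if (anyDuplicated(points)) stop("duplicate point coordinates")
  structure(
    list(points = points, frame_height = as.integer(frame_height),
         frame_width = as.integer(frame_width), label = label),
    class = "point_map"
  )
}

#' Number of points in a point map
#' @param x a `point_map`.
#' @export
n_points <- function(x) {
  stopifnot(inherits(x, "point_map"))
  nrow(x$points)
}

#' @export
print.point_map <- function(x, ...) {
  cat(sprintf("<point_map [%s] %d points in %d x %d frame>\n",
              x$label, nrow(x$points), x$frame_height, x$frame_width))
  invisible(x)
}

# ---- PGM raster I/O ---------------------------------------------------
# NetPBM PGM is the raster format: P2 (ASCII) and P5 (raw) at maxval
# 255. It is the simplest open container for an 8-bit grayscale raster
# and round-trips bit-exactly.

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P5", "P3", "P6")) {
    stop(sprintf("not an 8-bit PGM/PPM file (magic '%s'): %s", magic, path))
  }
  rgb <- magic %in% c("P3", "P6")
  # tokenizer skipping whitespace and '#' comments
  next_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || ch == "") {
        if (nzchar(tok)) return(tok)
        stop(sprintf("truncated PGM header: %s", path))
      }
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "" || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok)
      } else {
        tok <- paste0(tok, ch)
      }
    }
  }
  w <- as.integer(next_token())
  h <- as.integer(next_token())
  maxval <- as.integer(next_token())
  if (is.na(w) || is.na(h) || is.na(maxval) || maxval > 255L || maxval < 1L) {
    stop(sprintf("unsupported PGM header in %s", path))
  }
  n <- as.double(w) * h * (if (rgb) 3 else 1)
  if (magic %in% c("P5", "P6")) {
    vals <- as.integer(readBin(con, "raw", n = n))
  } else {
    vals <- integer(0)
    while (length(vals) < n) {
      chunk <- scan(con, what = integer(), n = n - length(vals),
                    quiet = TRUE, comment.char = "#")
      if (length(chunk) == 0L) break
      vals <- c(vals, chunk)
    }
  }
  if (length(vals) < n) stop(sprintf("truncated PGM pixel data: %s", path))
  vals <- vals[seq_len(n)]
  if (rgb) {
    # collapse RGB rasters only when every pixel has equal channels
    ch <- matrix(vals, ncol = 3L, byrow = TRUE)
    if (any(ch[, 1L] != ch[, 2L]) || any(ch[, 1L] != ch[, 3L])) {
      stop(sprintf("multi-channel raster with unequal channels: %s", path))
    }
    vals <- ch[, 1L]
  }
  # PGM stores row-major from the top row
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(mat, path, type = c("P5", "P2")) {
  type <- match.arg(type)
  stopifnot(is.matrix(mat), all(mat >= 0), all(mat <= 255))
  h <- nrow(mat)
  w <- ncol(mat)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("%s\n%d %d\n255\n", type, w, h), con, eos = NULL)
  vals <- as.integer(t(mat)) # row-major
  if (type == "P5") {
    writeBin(as.raw(vals), con)
  } else {
    lines <- vapply(seq_len(h), function(i) {
      paste(vals[((i - 1L) * w + 1L):(i * w)], collapse = " ")
    }, character(1))
    writeChar(paste0(paste(lines, collapse = "\n"), "\n"), con, eos = NULL)
  }
  invisible(NULL)
}

#' Read an 8-bit grayscale raster
#'
#' Reads a PGM (P2 or P5) file into a [grayscale_image]. The physical
#' pixel size is not stored in PGM; pass it explicitly (default 10
#' microns/pixel, the 6 mm / 600 px export geometry — see
#' [export_pixel_size()]).
#'
#' @param path path to a PGM file.
#' @param pixel_size_um microns per pixel.
#' @return A [grayscale_image].
#' @export
read_grayscale <- function(path, pixel_size_um = 10) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  grayscale_image(read_pgm(path), pixel_size_um = pixel_size_um)
}

#' Write an 8-bit grayscale raster
#'
#' @param image a [grayscale_image].
#' @param path output path (PGM).
#' @param type `"P5"` (raw, default) or `"P2"` (ASCII).
#' @export
write_grayscale <- function(image, path, type = c("P5", "P2")) {
  stopifnot(inherits(image, "grayscale_image"))
  write_pgm(image$intensities, path, type = match.arg(type))
  invisible(NULL)
}

#' Write a binary mask as an 8-bit raster
#'
#' Foreground pixels are written as 255 and background as 0, matching
#' the 255/0 vessel/stroma convention of the binarized C-scan map.
#'
#' @param mask a [binary_mask].
#' @param path output path (PGM).
#' @param type `"P5"` (raw, default) or `"P2"` (ASCII).
#' @export
write_mask <- function(mask, path, type = c("P5", "P2")) {
  stopifnot(inherits(mask, "binary_mask"))
  m <- matrix(0L, nrow(mask$foreground), ncol(mask$foreground))
  m[mask$foreground] <- 255L
  write_pgm(m, path, type = match.arg(type))
  invisible(NULL)
}

#' Read a binary mask from an 8-bit raster
#'
#' Any nonzero pixel becomes foreground.
#'
#' @param path path to a PGM file.
#' @param semantics foreground meaning; see [binary_mask()].
#' @return A [binary_mask].
#' @export
read_mask <- function(path, semantics = "vessel") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  binary_mask(read_pgm(path) != 0L, semantics = semantics)
}

#' Write a point set to CSV
#'
#' Columns `row,col,label`, 0-based coordinates. Reading the file back
#' with [read_points_csv()] reproduces the point map exactly.
#'
#' @param points a [point_map].
#' @param path output CSV path.
#' @export
write_points_csv <- function(points, path) {
  stopifnot(inherits(points, "point_map"))
  df <- points$points
  df$label <- rep(points$label, nrow(df))
  if (nrow(df) == 0L) {
    df <- data.frame(row = integer(0), col = integer(0), label = character(0))
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Read a point set from CSV
#'
#' @param path CSV with header `row,col,label`.
#' @param frame_height,frame_width frame dimensions the points live in.
#' @param label override the label; default taken from the file (must
#'   be unique there), falling back to `"observed"` for an empty file.
#' @return A [point_map].
#' @export
read_points_csv <- function(path, frame_height, frame_width, label = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("row", "col") %in% names(df))) {
    stop(sprintf("missing row/col columns in %s", path))
  }
  if (is.null(label)) {
    labs <- unique(df$label)
    label <- if (length(labs) == 1L) labs else "observed"
  }
  point_map(df[, c("row", "col")], frame_height, frame_width, label = label)
}

# Internal guard used across modules.
check_same_dim <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("dimension mismatch between %s: %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  }
  invisible(NULL)
}
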