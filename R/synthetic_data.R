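#' Synthetic eye specification
#'
#' Parameters of the synthetic stand-in for patient imagery: a
#' C-scan-like raster of dark tubular vessels on a brighter stroma
#' background, retinal-vessel-like exclusion strips, and a lesion
#' point set whose affinity for vessels is tunable from uniform
#' (`affinity = 0`, the null) to strongly vessel-attracted.
#'
#' Lesions are sampled without replacement with weight
#' `w(p) = 1 + affinity * exp(-d(p) / decay_lambda)` where `d(p)` is
#' the distance (pixels) to the nearest vessel pixel (0 on vessels).
#'
#' @param height,width frame size in pixels (default 600x600, the
#'   6 mm / 10 um-per-pixel export).
#' @param target_vessel_fraction vessel area fraction to aim for
#'   (default 0.45; achieved within +/- 0.05).
#' @param vessel_width_px range (min, max) of tube widths in pixels,
#'   default `c(5, 25)`.
#' @param vessel_intensity range of tube intensities, default
#'   `c(10, 50)` — entirely below the default threshold of 60.
#' @param stroma_intensity range of background intensities, default
#'   `c(120, 200)` — entirely above the threshold.
#' @param noise_sd Gaussian intensity noise SD, default 8 (keeps both
#'   classes > 8 SDs away from the threshold).
#' @param n_lesions lesion count, default 414 (the emulated cohort
#'   mean).
#' @param affinity vessel attraction strength, >= 0; 0 is the uniform
#'   null.
#' @param decay_lambda attraction decay length in pixels, default 3.
#' @param exclusion_n_strips number of vertical exclusion strips,
#'   default 3 (total area fraction about 0.05).
#' @param exclusion_fraction total exclusion area fraction, default
#'   0.05.
#' @param min_separation_px minimum Chebyshev distance between lesion
#'   centers, default 3, so the 2x2 paint marks of
#'   [generate_marked_ir()] can never merge; set 0/1 to disable (e.g.
#'   when checking the closed-form weight expectation).
#' @param mark_margin_px lesions keep this margin from the bottom and
#'   right frame edges so 2x2 marks stay in frame (default 1).
#' @param seed master seed for the eye.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(height = 600, width = 600,
                           target_vessel_fraction = 0.45,
                           vessel_width_px = c(5, 25),
                           vessel_intensity = c(10, 50),
                           stroma_intensity = c(120, 200),
                           noise_sd = 8,
                           n_lesions = 414,
                           affinity = 0,
                           decay_lambda = 3,
                           exclusion_n_strips = 3,
                           exclusion_fraction = 0.05,
                           min_separation_px = 3,
                           mark_margin_px = 1,
                           seed = 1L) {
  stopifnot(height > 0, width > 0,
            target_vessel_fraction > 0, target_vessel_fraction < 1,
            length(vessel_width_px) == 2, vessel_width_px[1] >= 1,
            diff(vessel_width_px) >= 0,
            all(vessel_intensity >= 0), all(vessel_intensity <= 255),
            all(stroma_intensity >= 0), all(stroma_intensity <= 255),
            max(vessel_intensity) < min(stroma_intensity),
            noise_sd >= 0, n_lesions >= 1, affinity >= 0,
            decay_lambda > 0, exclusion_n_strips >= 0,
            exclusion_fraction >= 0, exclusion_fraction < 1,
            min_separation_px >= 0, mark_margin_px >= 0)
  structure(
    list(height = as.integer(height), width = as.integer(width),
         target_vessel_fraction = target_vessel_fraction,
         vessel_width_px = vessel_width_px,
         vessel_intensity = vessel_intensity,
         stroma_intensity = stroma_intensity,
         noise_sd = noise_sd,
         n_lesions = as.integer(n_lesions),
         affinity = affinity, decay_lambda = decay_lambda,
         exclusion_n_strips = as.integer(exclusion_n_strips),
         exclusion_fraction = exclusion_fraction,
         min_separation_px = as.integer(min_separation_px),
         mark_margin_px = as.integer(mark_margin_px),
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Stamp a disc of the given radius at integer centers into a logical
# matrix; returns the updated matrix.
stamp_discs <- function(mask, centers, radius) {
  r <- max(1L, as.integer(floor(radius)))
  off <- expand.grid(dr = -r:r, dc = -r:r)
  off <- off[off$dr^2 + off$dc^2 <= radius^2, , drop = FALSE]
  rows <- rep(centers[, 1L], each = nrow(off)) + off$dr
  cols <- rep(centers[, 2L], each = nrow(off)) + off$dc
  ok <- rows >= 1L & rows <= nrow(mask) & cols >= 1L & cols <= ncol(mask)
  mask[cbind(rows[ok], cols[ok])] <- TRUE
  mask
}

# One random-walk tube centerline: starts on a random frame edge
# heading inward, takes unit steps with small heading jitter, ends on
# exit or after a step cap. Returns integer centers (1-based).
random_tube_centerline <- function(h, w) {
  side <- sample(4L, 1L)
  pos <- switch(side,
                c(1, runif(1, 1, w)),          # top
                c(h, runif(1, 1, w)),          # bottom
                c(runif(1, 1, h), 1),          # left
                c(runif(1, 1, h), w))          # right
  heading <- switch(side,
                    runif(1, pi / 4, 3 * pi / 4),
                    runif(1, -3 * pi / 4, -pi / 4),
                    runif(1, -pi / 4, pi / 4),
                    runif(1, 3 * pi / 4, 5 * pi / 4))
  max_steps <- 3L * (h + w)
  out <- matrix(0, nrow = max_steps, ncol = 2L)
  k <- 0L
  repeat {
    k <- k + 1L
    out[k, ] <- pos
    heading <- heading + rnorm(1, 0, 0.12)
    pos <- pos + c(sin(heading), cos(heading))
    if (pos[1] < 1 || pos[1] > h || pos[2] < 1 || pos[2] > w ||
        k >= max_steps) break
  }
  round(out[seq_len(k), , drop = FALSE])
}

#' Generate a synthetic C-scan and its ground-truth vessel mask
#'
#' Renders smooth random tubes (random-walk centerlines stroked at
#' sampled widths) at vessel intensities on a stroma background with a
#' gentle illumination gradient, adds Gaussian noise clipped to
#' [0, 255]. Tubes are added until the vessel area fraction is within
#' +/- 0.05 of the target.
#'
#' @param spec a [synthetic_spec()].
#' @param seed seed; defaults to `spec$seed`.
#' @return List with `cscan` (a [grayscale_image]) and `truth` (a
#'   vessel [binary_mask]).
#' @export
generate_vessel_image <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(seed, {
    h <- spec$height
    w <- spec$width
    target <- spec$target_vessel_fraction
    tol <- 0.045
    truth <- matrix(FALSE, h, w)
    vessel_int <- matrix(NA_integer_, h, w)
    attempts <- 0L
    while (mean(truth) < target - tol) {
      attempts <- attempts + 1L
      if (attempts > 1000L) {
        stop("generation error: vessel fraction target not attainable")
      }
      width_px <- runif(1, spec$vessel_width_px[1], spec$vessel_width_px[2])
      cl <- random_tube_centerline(h, w)
      cand <- stamp_discs(truth, cl, width_px / 2)
      if (mean(cand) > target + tol) {
        # too big a bite near the target: retry with the thinnest tube
        cand <- stamp_discs(truth, cl, spec$vessel_width_px[1] / 2)
        if (mean(cand) > target + tol) next
      }
      new_px <- cand & !truth
      vessel_int[new_px] <- as.integer(round(runif(
        1, spec$vessel_intensity[1], spec$vessel_intensity[2])))
      truth <- cand
    }
    # stroma background with a mild horizontal illumination gradient
    s_lo <- spec$stroma_intensity[1]
    s_hi <- spec$stroma_intensity[2]
    ramp <- matrix(rep(seq(0.3, 0.7, length.out = w), each = h), h, w)
    img <- s_lo + (s_hi - s_lo) * ramp
    img[truth] <- vessel_int[truth]
    if (spec$noise_sd > 0) {
      img <- img + rnorm(length(img), 0, spec$noise_sd)
    }
    img <- matrix(pmin(pmax(round(img), 0), 255), h, w)
    list(cscan = grayscale_image(img), truth = binary_mask(truth, "vessel"))
  })
}

#' Generate a retinal-vessel-like exclusion mask
#'
#' Vertical strips of jittered widths at random columns, totalling
#' about `exclusion_fraction` of the frame (default 5%), mimicking
#' retinal-vessel shadow artifacts removed from the analysis.
#'
#' @param spec a [synthetic_spec()].
#' @param seed seed; defaults to `spec$seed`.
#' @return A [binary_mask] with `semantics = "exclusion"`.
#' @export
generate_exclusion_mask <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(seed, {
    h <- spec$height
    w <- spec$width
    fg <- matrix(FALSE, h, w)
    n <- spec$exclusion_n_strips
    if (n > 0L && spec$exclusion_fraction > 0) {
      base_w <- spec$exclusion_fraction * w / n
      starts <- sort(sample.int(w, n))
      for (s in starts) {
        sw <- max(1L, as.integer(round(base_w * runif(1, 0.7, 1.3))))
        cols <- s:min(w, s + sw - 1L)
        fg[, cols] <- TRUE
      }
    }
    binary_mask(fg, "exclusion")
  })
}

# Sampling support for lesions: analysis region minus the bottom/right
# mark margin.
lesion_support <- function(region, spec) {
  sup <- region$foreground
  m <- spec$mark_margin_px
  if (m > 0L) {
    h <- nrow(sup)
    w <- ncol(sup)
    sup[(h - m + 1L):h, ] <- FALSE
    sup[, (w - m + 1L):w] <- FALSE
  }
  sup
}

# Per-pixel sampling weight field of the lesion model.
lesion_weight_field <- function(truth, spec) {
  d <- compute_distance_field(truth)$distance
  1 + spec$affinity * exp(-d / spec$decay_lambda)
}

#' Closed-form expected on-vessel fraction of the lesion model
#'
#' For the weight field `w(p) = 1 + affinity * exp(-d(p)/lambda)` over
#' the sampling support, the single-draw probability of landing on a
#' vessel pixel is `sum_vessel w / sum_support w`. Used as the
#' analytic reference for parameter-recovery checks.
#'
#' @param truth ground-truth vessel [binary_mask].
#' @param region analysis-region [binary_mask].
#' @param spec a [synthetic_spec()].
#' @return Expected on-vessel fraction in `[0, 1]`.
#' @export
expected_on_vessel_fraction <- function(truth, region, spec) {
  stopifnot(inherits(truth, "binary_mask"), inherits(region, "binary_mask"))
  w <- lesion_weight_field(truth, spec)
  sup <- lesion_support(region, spec)
  sum(w[sup & truth$foreground]) / sum(w[sup])
}

#' Sample synthetic lesion locations
#'
#' Draws `n_lesions` distinct pixels from the analysis region with
#' weight `1 + affinity * exp(-d/lambda)` (exact successive weighted
#' sampling without replacement via exponential keys). With
#' `min_separation_px > 1`, candidates closer than that Chebyshev
#' distance to an accepted lesion are skipped so paint marks cannot
#' merge.
#'
#' @param truth ground-truth vessel [binary_mask].
#' @param region analysis-region [binary_mask].
#' @param spec a [synthetic_spec()].
#' @param seed seed; defaults to `spec$seed`.
#' @return A [point_map] with `label = "observed"`.
#' @export
generate_lesions <- function(truth, region, spec, seed = spec$seed) {
  stopifnot(inherits(truth, "binary_mask"), inherits(region, "binary_mask"))
  check_same_dim(truth$foreground, region$foreground,
                 "truth and region masks")
  h <- nrow(truth$foreground)
  w <- ncol(truth$foreground)
  sup <- lesion_support(region, spec)
  idx <- which(sup)
  n <- spec$n_lesions
  if (n > length(idx)) {
    stop(sprintf("capacity error: %d lesions requested from a %d-pixel region",
                 n, length(idx)))
  }
  uniform <- spec$affinity == 0
  wt <- if (uniform) NULL else lesion_weight_field(truth, spec)[idx]
  with_seed(seed, {
    sep <- spec$min_separation_px
    if (uniform && sep <= 1L) {
      # plain uniform draw; identical in law to the key construction
      sel <- sample(idx, n, replace = FALSE)
      ord <- NULL
    } else {
      keys <- if (uniform) rexp(length(idx)) else rexp(length(idx)) / wt
      # partial selection: the greedy pass rarely consumes more than a
      # few candidates per accepted point, so rank only the smallest
      # keys and fall back to a full ordering if that pool runs dry
      m <- min(length(idx), 4L * n + 100L)
      if (m < length(idx)) {
        thr <- sort(keys, partial = m)[m]
        pool <- which(keys <= thr)
        ord <- idx[pool[order(keys[pool])]]
      } else {
        ord <- idx[order(keys)]
      }
      sel <- NULL
    }
    if (is.null(sel) && sep <= 1L) {
      sel <- ord[seq_len(n)]
    } else if (is.null(sel)) {
      greedy <- function(ordvec) {
        acc <- matrix(FALSE, h, w)
        out <- integer(n)
        got <- 0L
        for (p in ordvec) {
          r <- (p - 1L) %% h + 1L
          c <- (p - 1L) %/% h + 1L
          r0 <- max(1L, r - sep + 1L)
          r1 <- min(h, r + sep - 1L)
          c0 <- max(1L, c - sep + 1L)
          c1 <- min(w, c + sep - 1L)
          if (!any(acc[r0:r1, c0:c1])) {
            acc[r, c] <- TRUE
            got <- got + 1L
            out[got] <- p
            if (got == n) break
          }
        }
        if (got < n) NULL else out
      }
      sel <- greedy(ord)
      if (is.null(sel) && length(ord) < length(idx)) {
        # truncated pool ran dry: rank every candidate and retry
        sel <- greedy(idx[order(keys)])
      }
      if (is.null(sel)) {
        stop("capacity error: separation constraint unsatisfiable")
      }
    }
    pts <- data.frame(row = (sel - 1L) %% h, col = (sel - 1L) %/% h)
    point_map(pts, h, w, label = "observed")
  })
}

#' Render a marked-IR raster from lesion points
#'
#' A mid-gray background with a bright 2x2 mark (value 255) whose
#' top-left pixel sits at each lesion center — the synthetic analogue
#' of a grader's paintbrush marks. Errors if any two centers are
#' within Chebyshev distance 2 (marks would merge).
#'
#' @param lesions a [point_map].
#' @param spec a [synthetic_spec()].
#' @param background background intensity, default 80.
#' @return A [grayscale_image].
#' @export
generate_marked_ir <- function(lesions, spec, background = 80) {
  stopifnot(inherits(lesions, "point_map"))
  h <- lesions$frame_height
  w <- lesions$frame_width
  pts <- lesions$points
  if (nrow(pts) > 1L) {
    # occupancy check: any pair within Chebyshev distance <= 2 merges
    occ <- matrix(FALSE, h, w)
    occ[cbind(pts$row + 1L, pts$col + 1L)] <- TRUE
    for (k in seq_len(nrow(pts))) {
      r <- pts$row[k] + 1L
      c <- pts$col[k] + 1L
      r0 <- max(1L, r - 2L); r1 <- min(h, r + 2L)
      c0 <- max(1L, c - 2L); c1 <- min(w, c + 2L)
      if (sum(occ[r0:r1, c0:c1]) > 1L) {
        stop("generation error: lesion marks would merge (centers < 3 px apart)")
      }
    }
  }
  img <- matrix(as.integer(background), h, w)
  if (nrow(pts) > 0L) {
    for (dr in 0:1) for (dc in 0:1) {
      rr <- pmin(pts$row + dr, h - 1L) + 1L
      cc <- pmin(pts$col + dc, w - 1L) + 1L
      img[cbind(rr, cc)] <- 255L
    }
  }
  grayscale_image(img)
}

#' Generate one complete synthetic eye
#'
#' Vessel image, exclusion mask, lesion set and marked-IR raster, each
#' driven by a seed derived from `spec$seed`, so the whole eye is
#' reproducible from one integer.
#'
#' @param spec a [synthetic_spec()].
#' @param eye_id identifier attached to the eye (default `"synthetic"`).
#' @return A `synthetic_eye`: list with `eye_id`, `cscan`, `truth`,
#'   `exclusion`, `lesions`, `marked_ir`, `spec`.
#' @export
generate_synthetic_eye <- function(spec, eye_id = "synthetic") {
  stopifnot(inherits(spec, "synthetic_spec"))
  vi <- generate_vessel_image(spec, seed = derive_seed(spec$seed, 1L))
  excl <- generate_exclusion_mask(spec, seed = derive_seed(spec$seed, 2L))
  region <- build_analysis_region(vi$cscan, excl)
  lesions <- generate_lesions(vi$truth, region, spec,
                              seed = derive_seed(spec$seed, 3L))
  marked <- generate_marked_ir(lesions, spec)
  structure(
    list(eye_id = eye_id, cscan = vi$cscan, truth = vi$truth,
         exclusion = excl, lesions = lesions, marked_ir = marked,
         spec = spec),
    class = "synthetic_eye"
  )
}

#' Generate a synthetic cohort of eyes
#'
#' Per-eye specs are jittered around the template: lesion counts are
#' drawn from a truncated normal around 414 (SD 71.5 * sqrt(17) —
#' the cohort-mean dispersion scaled back to per-eye level), truncated
#' to [50, 1000]; vessel-fraction targets get +/- 0.03 uniform jitter.
#' Each eye's seed derives deterministically from the master seed.
#'
#' @param n_eyes number of eyes, >= 2 (default 17).
#' @param spec_template a [synthetic_spec()] used as the base.
#' @param seed master seed.
#' @return List of `synthetic_eye` objects.
#' @export
generate_cohort <- function(n_eyes = 17, spec_template = synthetic_spec(),
                            seed = 1L) {
  stopifnot(n_eyes >= 2, inherits(spec_template, "synthetic_spec"))
  params <- with_seed(seed, {
    sd_lesions <- 71.5 * sqrt(17)
    n_les <- vapply(seq_len(n_eyes), function(i) {
      repeat {
        x <- round(rnorm(1, 414, sd_lesions))
        if (x >= 50 && x <= 1000) return(as.integer(x))
      }
    }, integer(1))
    vf <- pmin(pmax(spec_template$target_vessel_fraction +
                      runif(n_eyes, -0.03, 0.03), 0.1), 0.85)
    list(n_les = n_les, vf = vf)
  })
  lapply(seq_len(n_eyes), function(i) {
    sp <- spec_template
    sp$n_lesions <- params$n_les[i]
    sp$target_vessel_fraction <- params$vf[i]
    sp$seed <- derive_seed(seed, 100L + i)
    generate_synthetic_eye(sp, eye_id = sprintf("eye%02d", i))
  })
}

#' Write a synthetic eye to a directory
#'
#' Emits `cscan.pgm`, `truth.pgm`, `exclusion.pgm`, `marked_ir.pgm`,
#' `lesions.csv` and `spec.json` — the on-disk form consumed by the
#' cohort pipeline.
#'
#' @param eye a `synthetic_eye`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_synthetic_eye <- function(eye, dir) {
  stopifnot(inherits(eye, "synthetic_eye"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_grayscale(eye$cscan, file.path(dir, "cscan.pgm"))
  write_mask(eye$truth, file.path(dir, "truth.pgm"))
  write_mask(eye$exclusion, file.path(dir, "exclusion.pgm"))
  write_grayscale(eye$marked_ir, file.path(dir, "marked_ir.pgm"))
  write_points_csv(eye$lesions, file.path(dir, "lesions.csv"))
  jsonlite::write_json(unclass(eye$spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
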