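test_that("vessel images hit the target fraction and are reproducible", {
  sp <- synthetic_spec(height = 300, width = 300, seed = 12)
  v1 <- generate_vessel_image(sp)
  frac <- mean(v1$truth$foreground)
  expect_gte(frac, sp$target_vessel_fraction - 0.05)
  expect_lte(frac, sp$target_vessel_fraction + 0.05)
  v2 <- generate_vessel_image(sp)
  expect_identical(v1$cscan$intensities, v2$cscan$intensities)
  expect_identical(v1$truth$foreground, v2$truth$foreground)
  v3 <- generate_vessel_image(sp, seed = 13)
  expect_false(identical(v1$truth$foreground, v3$truth$foreground))
})

test_that("noiseless generation is recovered exactly by thresholding", {
  sp <- synthetic_spec(height = 250, width = 250, noise_sd = 0, seed = 8)
  v <- generate_vessel_image(sp)
  got <- binarize_vessels(v$cscan, analysis_config(vessel_threshold = 60))
  expect_identical(got$foreground, v$truth$foreground)
})

test_that("lesion sampling matches its closed-form on-vessel expectation", {
  # full-size frame: at 10^4 of ~3.6e5 pixels the without-replacement
  # depletion stays well inside the binomial band
  sp <- synthetic_spec(n_lesions = 10000, affinity = 5, decay_lambda = 3,
                       min_separation_px = 0, seed = 99)
  v <- generate_vessel_image(sp)
  region <- build_analysis_region(v$cscan, NULL)
  expected <- expected_on_vessel_fraction(v$truth, region, sp)
  les <- generate_lesions(v$truth, region, sp, seed = 3)
  got <- mean(v$truth$foreground[cbind(les$points$row + 1L,
                                       les$points$col + 1L)])
  se <- sqrt(expected * (1 - expected) / sp$n_lesions)
  expect_lt(abs(got - expected), 3 * se)
})

test_that("affinity 0 is uniform and the infinite limit is vessel-bound", {
  sp0 <- synthetic_spec(height = 250, width = 250, n_lesions = 5000,
                        affinity = 0, min_separation_px = 0, seed = 5)
  v <- generate_vessel_image(sp0)
  region <- build_analysis_region(v$cscan, NULL)
  sup_frac <- {
    sup <- choropoint:::lesion_support(region, sp0)
    sum(v$truth$foreground & sup) / sum(sup)
  }
  les <- generate_lesions(v$truth, region, sp0, seed = 2)
  got <- mean(v$truth$foreground[cbind(les$points$row + 1L,
                                       les$points$col + 1L)])
  expect_lt(abs(got - sup_frac),
            3 * sqrt(sup_frac * (1 - sup_frac) / 5000))

  sp_inf <- synthetic_spec(height = 250, width = 250, n_lesions = 400,
                           affinity = 1e12, decay_lambda = 0.05,
                           min_separation_px = 0, seed = 5)
  les_inf <- generate_lesions(v$truth, region, sp_inf, seed = 4)
  expect_true(all(v$truth$foreground[cbind(les_inf$points$row + 1L,
                                           les_inf$points$col + 1L)]))
})

test_that("lesions respect region, margin, separation and capacity", {
  sp <- synthetic_spec(height = 120, width = 120, n_lesions = 200, seed = 3)
  v <- generate_vessel_image(sp)
  excl <- generate_exclusion_mask(sp)
  region <- build_analysis_region(v$cscan, excl)
  les <- generate_lesions(v$truth, region, sp)
  expect_equal(n_points(les), 200L)
  pts <- les$points
  expect_true(all(region$foreground[cbind(pts$row + 1L, pts$col + 1L)]))
  expect_true(all(pts$row <= 118L & pts$col <= 118L)) # mark margin
  # pairwise Chebyshev separation >= 3
  dmin <- min(vapply(seq_len(nrow(pts)), function(i) {
    d <- pmax(abs(pts$row - pts$row[i]), abs(pts$col - pts$col[i]))
    min(d[-i])
  }, numeric(1)))
  expect_gte(dmin, 3)
  sp_big <- synthetic_spec(height = 120, width = 120, n_lesions = 20000,
                           seed = 3)
  expect_error(generate_lesions(v$truth, region, sp_big), "capacity")
})

test_that("marked-IR rasters round-trip through lesion extraction", {
  for (k in c(1, 50)) {
    eye <- small_world(seed = 200 + k, n_lesions = k)
    pts <- extract_lesion_points(eye$marked_ir)
    expect_equal(n_points(pts), k)
    expect_true(all(chebyshev_match(eye$lesions$points, pts$points) <= 1))
  }
  # zero lesions: background only
  bg <- generate_marked_ir(point_map(data.frame(row = integer(0),
                                                col = integer(0)),
                                     50, 50), synthetic_spec(seed = 1))
  expect_equal(unique(as.vector(bg$intensities)), 80L)
  # marks closer than 3 px would merge: generation refuses
  close_pts <- point_map(data.frame(row = c(5L, 7L), col = c(5L, 5L)),
                         50, 50)
  expect_error(generate_marked_ir(close_pts, synthetic_spec(seed = 1)),
               "merge")
})

test_that("cohort generation jitters specs deterministically", {
  tpl <- synthetic_spec(height = 150, width = 150, n_lesions = 100, seed = 1)
  co1 <- generate_cohort(3, tpl, seed = 77)
  co2 <- generate_cohort(3, tpl, seed = 77)
  expect_equal(length(co1), 3L)
  expect_identical(lapply(co1, function(e) e$lesions$points),
                   lapply(co2, function(e) e$lesions$points))
  expect_identical(co1[[1]]$cscan$intensities, co2[[1]]$cscan$intensities)
  co3 <- generate_cohort(3, tpl, seed = 78)
  expect_false(identical(co1[[1]]$lesions$points, co3[[1]]$lesions$points))
  ns <- vapply(co1, function(e) e$spec$n_lesions, integer(1))
  expect_true(all(ns >= 50 & ns <= 1000))
  expect_error(generate_cohort(1, tpl, seed = 1), "n_eyes >= 2")
})

test_that("synthetic eyes export to a directory and read back", {
  eye <- small_world(seed = 301, n_lesions = 60, height = 150, width = 150)
  dir <- withr::local_tempdir()
  write_synthetic_eye(eye, dir)
  expect_true(all(file.exists(file.path(
    dir, c("cscan.pgm", "truth.pgm", "exclusion.pgm", "marked_ir.pgm",
           "lesions.csv", "spec.json")))))
  cs <- read_grayscale(file.path(dir, "cscan.pgm"))
  expect_identical(cs$intensities, eye$cscan$intensities)
  les <- read_points_csv(file.path(dir, "lesions.csv"), 150, 150)
  expect_identical(les$points, eye$lesions$points)
})
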