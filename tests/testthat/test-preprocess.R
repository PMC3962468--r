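test_that("vessel binarization follows the inclusive threshold rule", {
  cfg <- analysis_config(vessel_threshold = 60)
  img <- gray(matrix(c(59L, 60L, 61L), 1, 3))
  expect_identical(as.vector(binarize_vessels(img, cfg)$foreground),
                   c(TRUE, TRUE, FALSE))
  # exhaustive sweep of every intensity against the stated predicate
  sweep <- gray(matrix(0:255, 16, 16))
  got <- binarize_vessels(sweep, cfg)$foreground
  expect_identical(got, matrix(0:255, 16, 16) <= 60)
  # bright-vessel polarity flips the comparison
  cfg_b <- analysis_config(vessel_threshold = 60, vessel_is_dark = FALSE)
  expect_identical(binarize_vessels(sweep, cfg_b)$foreground,
                   matrix(0:255, 16, 16) >= 60)
  # degenerate extremes are legal and messaged
  expect_message(all_v <- binarize_vessels(gray(matrix(0L, 4, 4)), cfg))
  expect_true(all(all_v$foreground))
  expect_message(no_v <- binarize_vessels(gray(matrix(255L, 4, 4)), cfg))
  expect_false(any(no_v$foreground))
})

test_that("binarization is monotone in the threshold", {
  set.seed(7)
  img <- gray(matrix(sample(0:255, 400, replace = TRUE), 20, 20))
  prev <- binarize_vessels(img, analysis_config(vessel_threshold = 0))
  for (thr in c(30, 60, 120, 255)) {
    cur <- binarize_vessels(img, analysis_config(vessel_threshold = thr))
    expect_true(all(cur$foreground[prev$foreground]))
    prev <- cur
  }
})

test_that("analysis region is the frame minus the exclusion", {
  img <- gray(matrix(100L, 8, 10))
  full <- build_analysis_region(img, NULL)
  expect_equal(sum(full$foreground), 80L)
  excl <- matrix(FALSE, 8, 10)
  excl[1:3, 1:4] <- TRUE
  reg <- build_analysis_region(img, binary_mask(excl, "exclusion"))
  expect_equal(sum(reg$foreground), 80L - 12L)
  expect_false(any(reg$foreground & excl))
  expect_warning(build_analysis_region(img,
                                       binary_mask(matrix(TRUE, 8, 10),
                                                   "exclusion")),
                 "empty")
  expect_error(build_analysis_region(img,
                                     binary_mask(matrix(FALSE, 3, 3),
                                                 "exclusion")),
               "mismatch")
})

test_that("lesion extraction yields one centroid point per mark", {
  pl <- plant_blobs(40, 40, k = 3, size = 2, seed = 5)
  pts <- extract_lesion_points(pl$image)
  expect_equal(n_points(pts), 3L)
  # a 2x2 mark centroid sits at (+.5, +.5); rounding half away from
  # zero places the point within Chebyshev distance 1 of the corner
  expect_true(all(chebyshev_match(pl$corners, pts$points) <= 1))

  single <- gray(`[<-`(matrix(0L, 30, 30), cbind(11L, 21L), 255L))
  p1 <- extract_lesion_points(single)
  expect_identical(p1$points, data.frame(row = 10L, col = 20L))

  empty <- gray(matrix(0L, 10, 10))
  expect_warning(p0 <- extract_lesion_points(empty), "no mark")
  expect_equal(n_points(p0), 0L)
})

test_that("diagonal-touching marks split by connectivity", {
  img <- matrix(0L, 10, 10)
  img[3, 3] <- 255L
  img[4, 4] <- 255L # touches (3,3) only diagonally
  g <- gray(img)
  expect_equal(n_points(extract_lesion_points(
    g, analysis_config(connectivity = 8))), 1L)
  expect_equal(n_points(extract_lesion_points(
    g, analysis_config(connectivity = 4))), 2L)
})

test_that("planted blobs of sizes 1-5 are recovered within 1 pixel", {
  for (size in 1:5) {
    pl <- plant_blobs(120, 120, k = 12, size = size, seed = 100 + size)
    pts <- extract_lesion_points(pl$image)
    expect_equal(n_points(pts), 12L)
    centers <- data.frame(row = pl$corners$row + (size - 1) / 2,
                          col = pl$corners$col + (size - 1) / 2)
    expect_true(all(chebyshev_match(centers, pts$points) <= 1))
  }
})

test_that("min_mark_area drops small components", {
  img <- matrix(0L, 20, 20)
  img[2, 2] <- 255L                 # area 1
  img[10:11, 10:11] <- 255L         # area 4
  g <- gray(img)
  expect_equal(n_points(extract_lesion_points(
    g, analysis_config(min_mark_area = 2))), 1L)
  expect_equal(n_points(extract_lesion_points(
    g, analysis_config(min_mark_area = 1))), 2L)
})

test_that("region filtering conserves points", {
  set.seed(3)
  pm <- point_map(unique(data.frame(row = sample(0:19, 30, TRUE),
                                    col = sample(0:19, 30, TRUE))),
                  20, 20, "observed")
  full <- binary_mask(matrix(TRUE, 20, 20), "analysis_region")
  res <- filter_points_by_region(pm, full)
  expect_identical(res$kept$points, pm$points)
  expect_equal(res$n_excluded, 0L)

  none <- binary_mask(matrix(FALSE, 20, 20), "analysis_region")
  res0 <- filter_points_by_region(pm, none)
  expect_equal(n_points(res0$kept), 0L)
  expect_equal(res0$n_excluded, n_points(pm))

  for (seed in 1:5) {
    set.seed(seed)
    reg <- binary_mask(matrix(runif(400) > 0.4, 20, 20), "analysis_region")
    r <- filter_points_by_region(pm, reg)
    expect_equal(n_points(r$kept) + r$n_excluded, n_points(pm))
    if (n_points(r$kept) > 0) {
      expect_true(all(reg$foreground[cbind(r$kept$points$row + 1L,
                                           r$kept$points$col + 1L)]))
    }
  }
})
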