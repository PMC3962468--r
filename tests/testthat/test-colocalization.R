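test_that("point classification matches the multiply-and-histogram route", {
  for (seed in 1:20) {
    set.seed(seed)
    h <- sample(10:25, 1)
    w <- sample(10:25, 1)
    fg <- matrix(runif(h * w) < runif(1, 0.1, 0.6), h, w)
    if (!any(fg)) fg[1, 1] <- TRUE
    m <- vmask(fg)
    n <- sample(0:30, 1)
    idx <- sample.int(h * w, n)
    pm <- point_map(data.frame(row = (idx - 1) %% h,
                               col = (idx - 1) %/% h), h, w, "observed")
    direct <- classify_points(pm, m)
    expect_identical(direct$n_vessel, classify_points_multiply(pm, m))
    expect_equal(direct$n_vessel + direct$n_stroma, n)
  }
})

test_that("degenerate point sets classify correctly", {
  m <- vmask(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  on_v <- point_map(data.frame(row = 0:1, col = c(0L, 0L)), 2, 2)
  res <- classify_points(on_v, m)
  expect_equal(res$n_vessel, 2L)
  expect_equal(res$n_stroma, 0L)
  empty <- point_map(data.frame(row = integer(0), col = integer(0)), 2, 2)
  res0 <- classify_points(empty, m)
  expect_equal(c(res0$n_vessel, res0$n_stroma), c(0L, 0L))
})

test_that("a 751-point worked example reproduces its percentages", {
  # one full-height vessel band at columns 0-1, so distance = col - 1
  h <- 300
  w <- 40
  fg <- matrix(FALSE, h, w)
  fg[, 1:2] <- TRUE
  m <- vmask(fg)
  f <- compute_distance_field(m)
  place <- function(n, cols) {
    slots <- expand.grid(row = 0:(h - 1), col = cols)
    slots[seq_len(n), ]
  }
  pts <- rbind(place(233, 0:1),    # over vessels
               place(297, 2:4),    # distances 1-3
               place(149, 5:7),    # distances 4-6
               place(72, 8:10))    # distances >= 7
  pm <- point_map(pts, h, w, "observed")
  cls <- classify_proximity(pm, f, m)
  s <- choropoint:::summarize_point_set(cls)
  expect_equal(s$n, 751L)
  expect_equal(s$n_vessel, 233L)
  expect_equal(round(s$pct_vessel), 31)
  expect_equal(s$n_stroma, 518L)
  expect_equal(round(s$stroma_bins$pct, 2),
               c(near_1_3 = 57.34, mid_4_6 = 28.76, far_ge7 = 13.90))
  expect_equal(sum(s$stroma_bins$pct), 100)
})

test_that("analyze_eye is deterministic and satisfies its invariants", {
  eye <- small_world(seed = 21, affinity = 1)
  r1 <- analyze_eye("e", eye$marked_ir, eye$cscan, eye$exclusion, seed = 5)
  r2 <- analyze_eye("e", eye$marked_ir, eye$cscan, eye$exclusion, seed = 5)
  expect_identical(r1, r2)
  r3 <- analyze_eye("e", eye$marked_ir, eye$cscan, eye$exclusion, seed = 6)
  expect_false(identical(r1$control, r3$control))

  for (r in list(r1, r3)) {
    expect_equal(r$n_included, r$n_marked - r$n_excluded)
    for (side in c("observed", "control")) {
      s <- r[[side]]
      expect_equal(s$n_vessel + s$n_stroma, r$n_included)
      expect_equal(s$pct_vessel + s$pct_stroma, 100)
      expect_equal(sum(s$stroma_bins$counts), s$n_stroma)
      if (s$n_stroma > 0) expect_equal(sum(s$stroma_bins$pct), 100)
    }
    expect_gt(r$vessel_area_fraction, 0)
    expect_lt(r$vessel_area_fraction, 1)
  }
})

test_that("uniform points land on vessels at the area fraction", {
  eye <- small_world(seed = 31, height = 300, width = 300)
  region <- build_analysis_region(eye$cscan, eye$exclusion)
  cfg <- analysis_config()
  vessels <- binarize_vessels(eye$cscan, cfg)
  vessels$foreground <- vessels$foreground & region$foreground
  frac <- sum(vessels$foreground) / sum(region$foreground)
  n <- 5e4
  ctl <- generate_control_points(n, region, seed = 17)
  res <- classify_points(ctl, vessels)
  se <- sqrt(frac * (1 - frac) / n)
  expect_lt(abs(res$n_vessel / n - frac), 3 * se)
})

test_that("eye results serialize with raw values", {
  eye <- small_world(seed = 41)
  r <- analyze_eye("e41", eye$marked_ir, eye$cscan, eye$exclusion, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_eye_result(r, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$n_included, r$n_included)
  expect_equal(back$observed$pct_vessel, r$observed$pct_vessel)
  expect_equal(back$vessel_area_fraction, r$vessel_area_fraction)
})
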