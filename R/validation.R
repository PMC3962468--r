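#' Monte Carlo calibration of the cohort test
#'
#' Simulates repeated synthetic cohorts and applies the paired
#' one-tailed test machinery to each, to measure the type-I error rate
#' (at `affinity = 0` the observed lesions are uniform, so rejections
#' should occur at about the alpha level) or, at positive affinity,
#' the rate at which the qualitative signature appears (observed
#' near-vessel stroma percentage above control, far percentage below).
#'
#' One bank of `n_eyes` vessel/exclusion worlds is generated from the
#' master seed and reused across cohorts; each cohort redraws the
#' lesion and control point sets. The calibration being measured is
#' that of the point sampling and test, conditional on the imaging
#' worlds, which keeps a 1,000-cohort run inside a few minutes.
#'
#' @param n_cohorts number of simulated cohorts.
#' @param n_eyes eyes per cohort (default 17).
#' @param spec_template a [synthetic_spec()]; its `affinity` is the
#'   simulated truth.
#' @param seed master seed.
#' @param alpha significance level for the rejection count.
#' @return A list: `rejection_rate` (share of cohorts with one-tailed
#'   paired p < alpha on the over-vessel percentage), `signature_rate`
#'   (share with mean observed near-percentage > control and mean
#'   observed far-percentage < control), `p_vessel` (per-cohort
#'   p-values), `n_cohorts`, `n_eyes`.
#' @export
simulate_cohort_calibration <- function(n_cohorts, n_eyes = 17,
                                        spec_template = synthetic_spec(),
                                        seed = 1L, alpha = 0.05) {
  stopifnot(n_cohorts >= 1, n_eyes >= 2,
            inherits(spec_template, "synthetic_spec"))
  # fixed per-eye worlds and lesion counts, jittered as in
  # generate_cohort()
  counts <- with_seed(seed, {
    sd_lesions <- 71.5 * sqrt(17)
    vapply(seq_len(n_eyes), function(i) {
      repeat {
        x <- round(rnorm(1, 414, sd_lesions))
        if (x >= 50 && x <= 1000) return(as.integer(x))
      }
    }, integer(1))
  })
  bank <- lapply(seq_len(n_eyes), function(i) {
    sp <- spec_template
    sp$n_lesions <- counts[i]
    sp$seed <- derive_seed(seed, 100L + i)
    vi <- generate_vessel_image(sp)
    excl <- generate_exclusion_mask(sp)
    region <- build_analysis_region(vi$cscan, excl)
    vessels <- binarize_vessels(vi$cscan, analysis_config())
    vessels$foreground <- vessels$foreground & region$foreground
    list(spec = sp, truth = vi$truth, region = region,
         vessels = vessels, field = compute_distance_field(vessels))
  })
  pct <- function(cls) {
    s <- summarize_point_set(cls)
    c(vessel = s$pct_vessel, near = s$stroma_bins$pct[["near_1_3"]],
      far = s$stroma_bins$pct[["far_ge7"]])
  }
  p_vessel <- numeric(n_cohorts)
  signature <- logical(n_cohorts)
  for (k in seq_len(n_cohorts)) {
    obs <- matrix(NA_real_, n_eyes, 3)
    ctl <- matrix(NA_real_, n_eyes, 3)
    for (i in seq_len(n_eyes)) {
      b <- bank[[i]]
      s_obs <- derive_seed(seed, 1000L + k * (2L * n_eyes) + 2L * i)
      s_ctl <- derive_seed(seed, 1000L + k * (2L * n_eyes) + 2L * i + 1L)
      les <- generate_lesions(b$truth, b$region, b$spec, seed = s_obs)
      con <- generate_control_points(b$spec$n_lesions, b$region, s_ctl)
      obs[i, ] <- pct(classify_proximity(les, b$field, b$vessels))
      ctl[i, ] <- pct(classify_proximity(con, b$field, b$vessels))
    }
    p_vessel[k] <- paired_one_tailed_t(obs[, 1], ctl[, 1], "greater")$p
    signature[k] <- mean(obs[, 2]) > mean(ctl[, 2]) &&
      mean(obs[, 3]) < mean(ctl[, 3])
  }
  list(rejection_rate = mean(p_vessel < alpha),
       signature_rate = mean(signature),
       p_vessel = p_vessel, n_cohorts = n_cohorts, n_eyes = n_eyes)
}
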