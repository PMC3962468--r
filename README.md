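# choropoint

Quantitative topographic colocalization of retinal lesion point
patterns with the choroidal vasculature.

## The problem

Reticular pseudodrusen (RPD) are macular lesions associated with
progression to advanced age-related macular degeneration. On infrared
reflectance (IR) fundus images they appear as grouped hyporeflective
spots; en face OCT C-scans taken just below the retinal pigment
epithelium show the superficial choroidal vessels as dark tubes on a
brighter stroma. A recurring clinical question is whether RPD sit
over, or cluster near, the choroidal vessels more than chance would
allow. `choropoint` is for image-analysis researchers who have, per
eye, a marked IR image (one small paint mark per lesion) and a
co-registered C-scan, and who want reproducible per-eye statistics
and cohort-level inference against a random-dot null.

## The method

Per eye, with lesion set $L$ and binarized vessel set $V$ (pixel
intensity $\le 60$, vessels dark; retinal-vessel artifact regions
excluded):

* each lesion is a single pixel (centroid of its mark component);
* $\hat p_{vessel} = |\{x \in L : x \in V\}| / |L|$;
* stroma lesions are binned by $b = \lceil d(x, V) \rceil$ with
  $d$ the **exact** Euclidean distance transform (pixels):
  $b \in \{1..3\}$, $\{4..6\}$, $\{\ge 7\}$ — 10–30, 40–60,
  $\ge 70\ \mu m$ at 10 µm/pixel (6 mm field, 600 px export);
* a count-matched control set is drawn uniformly without replacement
  from the same analysis region and measured identically;
* across eyes, observed vs control percentages are compared with a
  paired one-tailed Student $t$ ($df = n_{eyes} - 1$), directions
  fixed a priori, results reported as mean ± SEM.

A complete synthetic-data generator (tubular vessel images, exclusion
strips, lesion sets with tunable vessel affinity
$w(p) = 1 + a e^{-d(p)/\lambda}$, marked-IR rasters) provides ground
truth for every stage; no patient data is included or required.

## Worked example

```r
library(choropoint)

# one synthetic eye with strong vessel affinity
sp  <- synthetic_spec(affinity = 5, n_lesions = 414, seed = 7)
eye <- generate_synthetic_eye(sp, eye_id = "demo")
analyze_eye("demo", eye$marked_ir, eye$cscan, eye$exclusion, seed = 1)
#> <eye_result demo: 414 marked, 0 excluded, 414 included>
#>   observed: 68.6% over vessels; stroma bins 46.2 / 16.9 / 36.9%
#>   control : 36.5% over vessels; stroma bins 17.1 / 14.1 / 68.8%
#>   vessel area fraction 0.422
```

414 marks were found, none fell in excluded regions; 68.6% of lesions
sit on vessel pixels against 36.5% of the matched random dots (the
region's vessel area fraction, 0.422, is what a uniform draw should
give), and the stroma lesions crowd the 1–3 px bin relative to
control — the attraction planted by `affinity = 5`.

```r
cohort  <- generate_cohort(6, synthetic_spec(affinity = 5, seed = 7), seed = 7)
results <- lapply(cohort, function(e)
  analyze_eye(e$eye_id, e$marked_ir, e$cscan, e$exclusion, seed = e$spec$seed))
summarize_cohort(results)
#> Cohort of 6 eyes (alpha = 0.05)
#>   pct_vessel   observed  68.5 +/-  0.9%  control  38.4 +/-  1.5%  diff +30.1  p = 1.17e-05 (greater) *
#>   pct_near_1_3 observed  41.0 +/-  3.0%  control  18.4 +/-  1.8%  diff +22.7  p = 0.000747 (greater) *
#>   pct_mid_4_6  observed  18.3 +/-  2.8%  control  14.8 +/-  1.3%  diff  +3.5  p = 0.212 (two_sided)
#>   pct_far_ge7  observed  40.7 +/-  4.1%  control  66.8 +/-  2.7%  diff -26.1  p = 0.00119 (less) *
```

Each row is one metric: observed and control mean ± SEM over eyes,
the mean paired difference, and the paired t-test p-value in the
pre-registered direction (`*` = significant at 0.05).

File-based runs use `run_cohort("config.json")` (see `?run_cohort`),
and `inst/cli/choropoint.R` exposes `simulate`, `analyze-eye` and
`analyze-cohort` subcommands.

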