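---
title: "Methods: lesion-to-vessel colocalization with a random-dot null"
author: "choropoint developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion-to-vessel colocalization with a random-dot null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choropoint)
```

## The question and the measurement model

Reticular pseudodrusen (RPD) are macular lesions, visible as grouped
hyporeflective spots on infrared-reflectance (IR) fundus images, whose
spatial relationship to the underlying choroidal vasculature is of
pathogenic interest. `choropoint` quantifies that relationship for a
cohort of eyes, given per-eye pairs of co-registered rasters:

1. a marked IR image, in which a grader has placed a small
   high-contrast paint mark on every lesion;
2. an en face OCT C-scan taken just below the retinal pigment
   epithelium, on which the superficial choroidal vessels appear dark
   against the brighter stroma;
3. optionally, a mask of retinal-vessel artifact regions to exclude.

The per-eye statistic set is simple by design. Each lesion is reduced
to a single pixel (the center of its mark). The C-scan is binarized
at a fixed intensity threshold into vessel vs stroma. A lesion either
sits on a vessel pixel or it does not; stroma lesions are binned by
their exact Euclidean distance $d$ to the nearest vessel pixel into
$\lceil d \rceil \in \{1..3\}$, $\{4..6\}$ and $\{\ge 7\}$ pixels
(10–30, 40–60, $\ge 70\ \mu m$ at the default export scale of
10 µm/pixel). Chance is represented by a count-matched set of uniform
random pixels drawn from the same analysis region, and cohort-level
inference compares observed and control percentages per eye with a
paired one-tailed Student $t$-test.

## Parameters that matter

* `vessel_threshold = 60` (intensity, 0–255). A pixel is vessel iff
  its intensity is `<= 60` with dark vessels. The threshold value is
  the one reported to discriminate choroidal vessels from stroma best
  on RPE-slab C-scans; the *inclusive* comparison at the boundary is
  this package's choice and is pinned by a unit test. Binarization is
  monotone in the threshold, so sensitivity analyses are cheap.
* `mark_threshold = 200`, `connectivity = 8`, `min_mark_area = 1`.
  Lesion extraction labels connected mark components and takes each
  component's centroid, rounded half-away-from-zero. For the 2×2
  marks the synthetic grader paints, the centroid falls on a
  half-integer corner and rounding shifts the point by one pixel
  diagonally; "recovered within 1 pixel" throughout this package
  means Chebyshev distance ≤ 1, the natural pixel-neighborhood
  metric. A maxima-based detector with a noise tolerance would need
  settings the source material does not state; the centroid of a flat
  mark is the stable equivalent.
* Distance bins by `ceiling(d)`. The binning source counts integer
  pixel distances (1–3, 4–6, ≥7) and never defines fractional
  handling; the ceiling rule makes the three bins exhaust the stroma
  lesions (every $d > 0$ lands in a bin starting at 1) and keeps the
  boundary cases unambiguous: $d = 6$ is mid, $d = 6.1$ is far. The
  distance transform itself is the exact Euclidean one (two-pass
  parabolic envelope in C++), not ImageJ's integer approximation:
  exactness is reproducible across implementations and the binning
  rule absorbs the difference.
* `min_lesions = 50`. Eyes with fewer included lesions are excluded
  at the cohort level, mirroring the study-design inclusion rule; the
  per-eye result object remains inspectable.
* Percent denominators: the over-vessel percentage uses the included
  lesion count; the three stroma-bin percentages use the stroma
  count. This matches the reporting convention the cohort numbers
  imply ("X% overlay the stroma, of which Y% were within 3 pixels").

## The null model

Controls are sampled uniformly **without replacement** from the
analysis region (frame minus exclusion), count-matched per eye.
Without replacement because two observed lesions can never share a
pixel in a single-point map; a collisions-allowed mode exists for
sensitivity checks only. Controls respect the same exclusion mask as
lesions so the comparison is like-for-like. One control realization
per eye is the primary design, matching the original analysis;
repeated-realization averaging is available by re-running with
different seeds.

## Cohort inference

Per metric the package reports observed and control mean ± SEM
(sample SD / $\sqrt{n}$), the mean paired difference, and a paired
Student $t$ on the per-eye differences with $n-1$ degrees of freedom.
Pairing is chosen because every control set is generated for, and
count-matched to, its own eye. Directions are fixed a priori — over
vessels and near (1–3 px): observed > control; far (≥7 px): observed
< control; the 4–6 px bin has no directional hypothesis and is
reported two-sided as the doubled smaller tail — and each output row
carries its direction to prevent silent sign errors. Eyes are treated
as independent units even when two eyes share a patient; no
within-patient correlation adjustment is made, a known limitation of
the design being emulated. Degenerate-variance differences raise an
explicit error rather than returning a fake p-value.

## The synthetic world

No patient imagery ships with the package; every pipeline stage is
exercised on synthetic eyes with known ground truth
(`synthetic_spec()`, `generate_synthetic_eye()`, `generate_cohort()`).

* **Vessels**: random-walk centerlines entering from the frame edge,
  stroked at widths 5–25 px, intensities 10–50 on a 120–200 stroma
  background with Gaussian noise (SD 8) — both intensity classes sit
  more than 8 SDs from the threshold of 60, so thresholding recovers
  the truth mask essentially exactly (and exactly at `noise_sd = 0`,
  which a test pins). Tubes are added until the vessel area fraction
  reaches the 0.45 target within ±0.05.
* **Lesions**: $n$ distinct pixels drawn with weight
  $w(p) = 1 + a\,e^{-d(p)/\lambda}$ ($d$ = distance to nearest vessel
  pixel, 0 on vessels). $a = 0$ is exactly the uniform null;
  $\lambda \to 0,\ a \to \infty$ concentrates all lesions on vessels.
  This additive family was chosen because its null is exactly uniform
  and its single-draw on-vessel probability has the closed form
  $\sum_{vessel} w / \sum_{support} w$
  (`expected_on_vessel_fraction()`), not for biological fidelity.
  Sampling uses exponential keys (`Exp(1)/w`, smallest $n$ kept),
  the exact successive-WOR distribution. Defaults: $n = 414$ lesions
  (the emulated cohort mean), $\lambda = 3$ px.
* **Separation**: lesion centers keep a Chebyshev distance ≥ 3
  (`min_separation_px`) so the 2×2 paint marks can never merge —
  with ~400 uniform lesions on a 600² frame about five merges would
  otherwise be expected per eye, silently breaking the count
  round-trip. The thinning is spatially neutral, but it is *not* part
  of the closed-form expectation, so expectation-recovery checks
  disable it.
* **Exclusion**: vertical strips totalling ~5% of the frame, a crude
  stand-in for retinal-vessel shadows. Lesions are never generated
  inside exclusions (the observed and control supports match).
* **Cohorts**: per-eye lesion counts are drawn from a normal around
  414 with SD $71.5\sqrt{17}$ (the reported cohort dispersion read as
  a SEM and scaled back to per-eye level), truncated to [50, 1000];
  vessel-fraction targets jitter by ±0.03. All per-eye seeds derive
  deterministically from one master seed.

What a green synthetic test does **not** establish: realism of OCT
speckle, RPE-contour artifacts, true choroidal branching topology, or
the behavior of the vessel threshold on real scanner output. The
synthetic world validates the *measurement chain and inference*, not
the imaging physics. One geometric consequence worth knowing: with
5–25 px tubes at 45% area fraction the stroma gaps are wider than in
a real dense choroid, so synthetic stroma lesions sit in the ≥7 px
bin far more often than the ~5–9% seen in patients.

## Monte Carlo validation design

`simulate_cohort_calibration()` measures (i) the type-I error of the
paired one-tailed test at `affinity = 0` (1,000 cohorts of 17 eyes;
the rejection rate must sit inside the 95% binomial band around
0.05) and (ii) the rate at which positive affinity reproduces the
qualitative signature (observed 1–3 px percentage above control, ≥7
px percentage below). One bank of 17 vessel/exclusion worlds is
generated per run and reused across cohorts, with fresh lesion and
control draws per cohort: the calibration under study is that of the
point sampling and test *conditional on the imaging worlds*, and
regenerating 17,000 vessel images would add runtime without touching
the quantity being validated.

## Numerical choices and degenerate inputs

* Exact EDT verified against an $O(NM)$ brute-force oracle on random
  masks (pinned to < 1e-12).
* All-stroma masks make the distance field undefined → explicit
  error; all-vessel or all-stroma binarizations are legal but logged.
* Empty analysis regions, empty point sets, and eyes failing any
  stage are per-eye fatal, recorded in the run manifest, and never
  block other eyes.
* Centroid rounding: half away from zero; points clamped to frame.
* Raw floats are written to JSON; display rounds to one decimal.
* Rasters travel as 8-bit NetPBM PGM (P2/P5), the simplest open
  format that round-trips bit-exactly with no binary dependency;
  masks are written 255 = foreground / 0 = background.

## Known limitations

Single fixed vessel threshold (no per-eye adaptive thresholding);
2D en face analysis only; no lesion-footprint (area) overlap — lesion
centers only, by design; no inter-eye correlation modeling; uniform
null only (no clustering-preserving null); the ImageJ "noise"-dot
mechanism of the original control generation is approximated by
uniform pixel sampling.
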