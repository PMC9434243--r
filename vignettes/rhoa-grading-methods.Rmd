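---
title: "DXA-based rHOA grading: models, calibration and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DXA-based rHOA grading: models, calibration and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhoadx)
library(dplyr)
```

## What the package computes

High-resolution DXA scans resolve the bony margins of the hip joint well
enough to score the two structural hallmarks of radiographic hip
osteoarthritis (rHOA): marginal osteophytes and joint space narrowing (JSN).
`rhoadx` implements the measurement and grading side of a semi-automated
workflow in which a point-placement model has already put 85 outline points
around the left femoral head and acetabulum, and a reader has marked up
osteophytes as polygons at up to three sites — the lateral acetabulum, the
superolateral femoral head and the inferomedial femoral head.

From those inputs the package computes, per participant:

* **Osteophyte area** at each site, in mm^2^, as the shoelace area of the
  auto-closed polygon scaled by the squared pixel spacing.
* **Superior minimum joint space width (mJSW)**, in mm: the minimum
  distance between the superior femoral head margin and the acetabular
  sourcil, each treated as a polyline. The minimum is taken over
  point-to-segment distances in both directions, which is robust to sparse
  landmark sampling (a pure point-to-point minimum overestimates the
  width).
* **Semi-quantitative grades.** Osteophytes: grade 1 at >= 1 mm^2^,
  grade 2 at a site-specific threshold (defaults 10 / 19 / 15 mm^2^ for
  acetabular / superior / inferior), grade 3 at >= 50 mm^2^; all
  thresholds inclusive. JSN: grade 3 whenever raw mJSW <= 1.5 mm (this
  rule takes precedence); otherwise grades 1-2 by cut-offs on
  height-adjusted mJSW.
* **Composite rHOA grade 0-4** from the sum of the three osteophyte grades
  and the JSN grade (0-12): sum 0 -> grade 0, 1 -> 1, 2-3 -> 2, 4-6 -> 3,
  7-12 -> 4. The weighting deliberately lets osteophytes alone carry a
  participant to high grades, reflecting evidence that osteophytes relate
  more strongly to symptoms than JSN does.

Downstream, the package reproduces the standard association pipeline:
prevalence tabulation, logistic regression of hip pain and
hospital-diagnosed hip OA (HES OA) on each exposure, Cox
proportional-hazards models of time to total hip replacement (THR),
adjustment for age, sex, height and weight, sex-interaction screens at
p < 0.1 with stratified estimates, and grade-0 reference groups
throughout.

## Conventions and degenerate inputs

Coordinates are image-space (x right, y down, origin top-left); all
reported distances are mm after pixel-spacing scaling. Polygons are
auto-closed; fewer than 3 vertices, self-intersection or zero area are
errors. The outline indices that bound the superior joint space are *not*
hard-coded: `region_map` is part of the input, because the index
convention belongs to the annotation tool, not to the method. The
synthetic generator ships a documented default
(`default_region_map()`: points 1-32 femoral head, 33-64 sourcil).
Records failing image QC (`hip_not_fully_visualized`, `poor_quality`,
`duplicate`) are excluded from grading and counted by reason in the run
manifest. A missing height falls back to raw-mJSW grading with a warning.
Missing osteophyte mark-up means "no osteophyte" (grade 0), matching the
source workflow where absence of annotation is absence of the feature.

## Calibration assumptions

Two pieces of the published grading scheme are not printed in full and are
therefore explicit, swappable configuration (`grading_config()`,
serialized as versioned JSON):

* **Per-site grade-2 osteophyte thresholds.** Only the range
  (>= 10-19 mm^2^ "depending on location") is public. The defaults
  10 / 19 / 15 mm^2^ respect that range and are flagged as assumptions.
* **Height adjustment of mJSW.** The published pipeline derives JSN
  grades 1-2 from height-adjusted mJSW without printing the formula. We
  use the simplest consistent model: linear mean-adjustment,
  `adjusted = raw - slope * (height - 170.1 cm)`, default slope
  0.012 mm/cm (the male-female mJSW gap of 0.16 mm over a 13.6 cm height
  gap implies ~0.012). Grade 1/2 cuts default to the 20th and 5th
  percentiles of a Normal(2.89, 0.7) reference adjusted-mJSW distribution
  (2.301 and 1.739 mm); mean 2.89 mm is the large-cohort mean, and
  sd 0.7 mm reproduces a realistic 0-6 mm range at n ~ 40 000. Users with
  a reference calibration should replace all of these in the config.

## The synthetic generators

No individual-level data from the source cohort can be redistributed, so
the package carries two generators that emulate its published summary
structure. Their defaults *are* the study conditions; they are not tuning
knobs.

**Geometry** (`generate_synthetic_hip()`): the superior femoral head is a
circular arc (default radius 25 mm), the sourcil a concentric arc offset
radially by the target mJSW. The offset carries a chord-sagitta correction
`R = r + w / cos(step / 2)` so that the *sampled polylines* sit exactly
`w` apart — without it the discretised arcs sit closer than the continuum
circles by `w (1 - cos(step / 2))`, which is visible at the 1e-3 mm level.
Osteophyte polygons are star-shaped 12-gons rescaled to the target area
exactly (rescaling after jitter, so noisy polygons still hit their area).
Landmark jitter is Gaussian per coordinate; note that a minimum over ~30
jittered vertex pairs is biased low by a few noise SDs, so mJSW targets
are only recovered to ~0.1 mm at noise sd 0.05 mm.

**Cohorts** (`simulate_cohort()`): demographics are truncated normals with
the published means and ranges (age 63.7 y [44-82], height 177.2/163.6 cm
and weight 83.2/68.2 kg by sex, 52.2% female). Endophenotype presence is
drawn per sex from probit thresholds on a shared latent severity
(Gaussian copula, correlation 0.45) with a linear age shift
(0.03 / year on the threshold scale); thresholds are solved numerically so
per-sex grade >= 1 prevalences hit the published targets (e.g. JSN 15.5%
male / 7.5% female). The shared latent makes site grades positively
correlated, as they are anatomically. Conditional grade distributions
given presence (osteophytes 0.55/0.35/0.10, JSN 0.70/0.22/0.08) are
plausible defaults, not published values. Outcomes: logistic models whose
intercepts are solved by `uniroot` so the marginal prevalence matches the
target exactly in expectation given the realised covariates (hip pain
8.1%, HES OA 1.3%); THR is exponential with the baseline rate solved so
0.6% of participants experience the event under uniform(3, 2437)-day
administrative censoring. Effect sizes enter as named log-OR / log-HR
vectors on exposure indicators; all default to zero. A second exposure
mode draws the composite grade directly from the published five-category
distribution (32 758 / 4 565 / 2 317 / 543 / 157 out of 40 340), used when
an analysis needs the composite-grade margins pinned — component-level
simulation cannot reproduce the 0.4% grade-4 prevalence because composite
grade 4 requires a sum >= 7 across largely rare features.

What the generator does *not* emulate: real age-sex-exposure-outcome
dependence beyond the declared gradients, intensity-level image features,
right hips, informative censoring, or correlated missingness. Passing
recovery tests therefore demonstrates the *estimation machinery* is
unbiased and calibrated under the declared data-generating process, not
that the published effect sizes would be recovered from other cohorts.

## Statistical choices

Logistic models are maximum-likelihood `glm` fits; Cox models use the
partial likelihood with Efron tie handling (ties arise because follow-up
is rounded to whole days). All intervals are Wald 95% CIs and standard
errors are model-based; no multiple-testing correction is applied, as the
pipeline mirrors an analysis that reported unadjusted p-values.
Single-grade contrasts (grade k vs grade 0) drop records at other grades
rather than pooling them. Complete-case analysis per model, with the
dropped count reported. Non-estimable cells (an empty exposure-outcome
cell, or no events in a group) are reported as such with the reason, never
silently dropped. The sex-interaction screen uses the conventional
p < 0.1 threshold on the Wald test of the exposure-by-sex product term.

## Validation design and problem sizes

The test suite validates three layers, each against an independent oracle:

* **Geometry**: shoelace area against fan triangulation (and
  `pracma::polyarea`) to 1e-9 on 100 random simple polygons; mJSW against
  a dense-resampling brute force (10^4 points per curve, original
  vertices retained, exact pruned point-pair minimum) to 1e-6 on 100
  random curve pairs; rigid-motion invariance and pixel-spacing
  homogeneity to 1e-9.
* **Grading**: all 4^4 = 256 component-grade combinations against a
  brute-force mapping written directly from the published rule; inclusive
  boundary behaviour at 1 mm^2^, 50 mm^2^ and 1.5 mm.
* **Recovery**: the five headline adjusted effects (hip-pain OR 2.05,
  HES-OA OR 4.98, THR HR 6.17 for any osteophyte; hip-pain OR 1.37 for
  JSN; THR HR 57.70 for composite grade 4) are planted in the generator
  and refitted at n = 40 340; the replicate-mean log effect must sit
  within 2 Monte-Carlo SEs of the truth (150 replicates per effect in the
  test suite, 50 in the reproduction script) and a single replicate must
  fall inside the published interval. With all effects null, the 95% CI
  for the any-osteophyte-hip-pain OR must cover 1 in 93-99 of 100
  replicates. The 2-MC-SE and coverage checks have irreducible
  false-alarm rates by construction (~5% and ~15%); replicate counts were
  chosen to keep suite runtime practical on one CPU while bounding the
  detectable bias at well under the ~10% scale that would matter for the
  reported quantities.

Known limitations: the geometry module measures, it does not place points;
the mJSW region convention for real data must come from the user; the
height-adjustment and grade-2 thresholds are assumptions until calibrated;
and the Cox model assumes proportional hazards and non-informative
censoring, neither of which is tested against violation.
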