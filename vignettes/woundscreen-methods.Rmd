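---
title: "Screening surgical wounds for infection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening surgical wounds for infection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundscreen)
```

## The screening problem

Surgical-site infection usually declares itself after discharge, and its
cardinal early sign on a photograph is peri-incisional erythema. The package
implements a fully automatic screen for stapled abdominal wounds: given a
patient-taken photograph and a seven-item symptom questionnaire, it outputs
"needs in-person review" or "satisfactory evolution". The design goal is a
*screen*, not a diagnosis: false positives cost an extra consultation, false
negatives cost a missed infection, so every asymmetric choice below leans
toward sensitivity.

## Fuzzy gray-scale morphology

Staples are localized with morphological operators generalized to fuzzy
logic. For a gray channel $f : \Omega \to [0,1]$ and structuring element
$B$ with memberships in $[0,1]$,

$$(f \ominus B)(x) = \inf_y I\bigl(B(y-x),\, f(y)\bigr), \qquad
  (f \oplus B)(x) = \sup_y C\bigl(B(x-y),\, f(y)\bigr),$$

where $C$ is a left-continuous t-norm and $I$ its residual implication. The
default pair is minimum/Gödel: with a crisp $B$ it reduces exactly to
classical flat morphology, which gives an independent oracle for testing,
and for full rectangular crisp elements the implementation switches to a
separable running-min/max fast path (tested equal to the generic operator).
The Łukasiewicz pair is available behind the same `fuzzy_logic_pair()`
switch. Out-of-image pixels are padded erosion-neutrally with 1 and
dilation-neutrally with 0, so the image border cannot generate spurious
staple responses. The white top-hat $f - \mathrm{open}(f)$ then isolates
bright structure too thin to contain the element.

## Staple detection and the wound axis

Detection runs the top-hat of the brightness (HSV value) channel with a
flat $7\times7$ square — wider than a staple leg (≈3 px at the 500-px scale)
but much shorter than one. Candidate pixels (response ≥ 0.08) are labelled
into connected components in deterministic row-major order, and components
survive four filters:

| filter | default | rationale |
|---|---|---|
| area | [max(15, 4·10⁻⁵·HW), 5·10⁻³·HW] | noise speckles below, dressings above |
| elongation (major/minor axis) | ≥ 2.5 | staples are bars, glare blobs are not |
| top-hat response | ≥ 0.08 | metallic staples on skin are high-contrast |
| median saturation | ≤ 0.35 | staples are gray; bright *skin* slivers (e.g. between two antiseptic stains) are chromatic |

The saturation gate earns its place: stress scenes with overlapping stain
patches produce thin bright strips of ordinary skin that pass the first
three filters but are strongly colored, and this was the single observed
source of phantom staples.

Staples straddle the incision, so the wound axis is the total-least-squares
line through the staple centroids (first principal component of their
scatter; direction sign fixed for determinism). The peri-wound ROI is the
band of half-width $2\times$ the median staple length around that axis,
clipped along the axis to the staple span plus one half-width. The axial
clip is a deliberate refinement of a plain infinite band: without it the
ROI crosses the whole frame and healthy skin far from the incision dilutes
the redness proportion roughly by the ratio of incision length to image
diagonal, compressing the dynamic range of the score. A plain band remains
available through `wound_roi(..., axial_halflength = NULL)`, and when fewer
than two staples are found the pipeline falls back to a whole-image ROI and
flags the axis as undeterminable rather than failing.

## Inpainting

Reconstruction under the staple mask is diffusion (harmonic) inpainting:
masked pixels are iterated to the mean of their 4-neighbours (Jacobi
sweeps on the mask's bounding box) until the largest update falls below
$10^{-5}$ or 500 iterations. Staple legs are ≈3 px thick, so convergence is
fast in practice; the method is deterministic, preserves constants exactly,
and provably never touches an unmasked pixel. Whether to score redness on
the inpainted image or simply to exclude staple pixels from the ROI is
genuinely open; both orders are exposed (`run_config(inpaint_first = )`)
with inpainting first as the default, since specular staple pixels that
survive an imperfect mask would otherwise bias the color measure.

## Redness proportion and the 0.63 cutoff

"Close to red" is a trapezoidal membership on the circular hue distance to
0°: full membership within 10°, support out to 30°, linear in between,
gated to zero when saturation < 0.25 or value < 0.2 (washed-out or dark
pixels carry no reliable hue). Achromatic pixels take hue 0 by convention
but are removed by the saturation gate. The image score is the *proportion*
of ROI pixels with membership ≥ 0.5 (a count, matching the operational
definition of the original screen); a membership-weighted mean is kept as a
sensitivity analysis. The infection call is `proportion ≥ 0.63`, ties
positive. The 0.63 default is the cutoff the original study derived by ROC
analysis on its own cohort; it is treated here as a configurable
calibration constant — `roc_and_cutoff()` (or the `calibrate` CLI command)
recalibrates it for any scored cohort, and the hue/saturation gates were
chosen for plausible skin/erythema separation, not fitted to any data.

## Questionnaire and triage fusion

The questionnaire has pain VAS 0–10 and six binary items (redness, burning,
opening, swelling, secretion, fever); all seven are mandatory, with no
imputation — an incomplete record is rejected outright. Fever is defined by
temperature strictly above 37.7 °C; when a binary answer and a temperature
disagree, the temperature wins with a warning, because the rule is
temperature-defined. Fusion is disjunctive: review when the image is
positive, OR any hard flag (opening, secretion, fever) is set, OR at least
3 of 6 symptoms are present, OR VAS ≥ 7. A union rule is the natural
sensitivity-first combination — it can only add sensitivity on top of the
image channel — and makes every trigger auditable in the decision's
`reasons`. The symptom-count and VAS cutoffs are this package's own
calibration constants, labelled as such. Monotonicity holds by
construction: turning a symptom on or increasing redness can never rescind
a review.

## Evaluation statistics

Sensitivity and specificity come with exact Clopper–Pearson 95% intervals
(`stats::binom.test`), chosen over asymptotic intervals because the
margins of interest are small (five infections). Cohen's
$\kappa = (p_o - p_e)/(1 - p_e)$ uses the standard marginal-product
expected agreement and refuses the degenerate both-raters-constant case.
The ROC sweeps thresholds over midpoints between consecutive unique scores
plus sentinels, computes AUC by the trapezoid rule (equal to the
Mann–Whitney statistic, and cross-checked against pROC in the tests), and
picks the cutoff maximizing Youden's $J$ with ties broken toward the lower
threshold — again the sensitivity-first direction. Metrics are computed at
the image level (the only unit at which the published 5/14/69/88 table is
arithmetically consistent), with a patient-level aggregation (positive if
any image positive) reported alongside.

## The synthetic generator

`generate_wound_image()` renders, in order: Gaussian-textured skin (base
RGB (0.80, 0.62, 0.45), SD 0.02), peri-incisional erythema, a dark incision
line (300 × 2 px through the centre, random orientation), translucent
antiseptic stain ellipses, a bright dressing pad anchored at a border, and
finally the staples (bright gray 0.92, 25 × 3 px, perpendicular to the
incision at 40 px spacing) — staples last because they physically sit on
top. Erythema blends the skin toward (0.70, 0.15, 0.20) with amplitude
`erythema_intensity · exp(−½ (d⊥/30)²)`, tapering likewise past the
incision ends; the scene is labelled infected when intensity > 0.5. This
construction makes the measured redness proportion strictly monotone in
intensity, which is the property the recovery tests exercise.

Cohorts mirror the study structure: two visits (days 3 and 10) per patient,
infection drawn per patient as Bernoulli(0.122 by default), intensity
uniform on [0.05, 0.45] for non-infected and [0.55, 0.95] for infected
wounds, and per-item symptom probabilities elevated under infection (e.g.
redness 0.9 vs 0.1, fever 0.5 vs 0.02). Everything derives from one seed;
cohorts are manifests plus per-image parameters, with images rendered
lazily so a 1000-patient manifest costs nothing.

What the generator does *not* emulate — and therefore what green tests do
not show about real photographs: illumination and white-balance variation
across phones, skin-tone diversity beyond a configurable base color,
specular glare, perspective and defocus, sutured or partially dehisced
closures, and real antiseptic chemistry. Passing the synthetic suites shows
the algorithms are correct and self-consistent under the stated generative
model, not that 0.63 or the membership gates transfer to any particular
clinic's images; the calibration path exists precisely because they may
not.

## Numerical choices and problem sizes

Brute-force oracle tests run on 8×8 (morphology) and 16×16 (redness)
rasters, 100 replicates each. End-to-end suites use 512×512 scenes: 50 for
staple/axis recovery (thresholds: exact count, axis within 10°, each in ≥
90% of scenes) and a 200-image cohort (100 patients × 2 visits) for ROC
recalibration, sized to keep the full suite comfortably on one CPU while
leaving the binomial margins meaningful. Component second moments carry the
1/12 single-pixel correction so 1-px-wide lines have finite elongation;
floating-point negatives in the top-hat are clamped at 0; all component
ordering is row-major for determinism.

## Known limitations

Single wound, staple closure only, no learning-based detection, no color
constancy. The κ = 0.8171 agreement and the 0.63 cutoff of the original
study are not re-derivable from published information (the underlying 363
ratings and images are not printed); the package therefore verifies its
statistics against independent brute-force implementations and its pipeline
against generator ground truth instead.
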