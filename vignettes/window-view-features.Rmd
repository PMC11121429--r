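---
title: "Quantifying window views: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying window views: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viewfeat)
```

## The problem

What people see from their windows — greenery, sky, built structure — is a
candidate environmental exposure for mental health. `viewfeat` implements a
complete analysis chain for studying this exposure from photographs of
residential window views:

1. **Feature extraction**: fourteen low-level visual features (LLVFs) per
   image — pixel statistics computed without any object recognition.
2. **Behavioral scoring**: a state negative-affect composite from a 20-item
   anxiety-depression inventory, and delay-discounting indifference points
   with their normalized area under the curve (AUC).
3. **Inference**: Spearman correlation matrices and bidirectional
   AIC-stepwise linear regression with forced-entry blocks, linking
   features, subjective view ratings, and outcomes.
4. **Simulation**: a synthetic scene-and-cohort generator with exact ground
   truth, because real window-view photo corpora are rarely shareable
   (privacy) and planted-truth recovery is the only way to validate the
   chain end to end.

## The fourteen features

Let an image be an `H x W` grid of 8-bit RGB pixels, converted to HSV.

* **Hue mean / SD** (features 1-2). Hue is angular: red at 0, cyan at
  ±π radians. The mean is the direction of the mean unit vector over all
  chromatic pixels, and the spread is the angular deviation
  `sqrt(2 (1 - R))` with `R` the mean resultant length. Achromatic pixels
  (saturation exactly 0) are excluded because their hue is undefined in the
  hexcone model; an all-achromatic image, or an antipodal hue distribution
  with `R ~ 0`, yields a flagged `NA` rather than a silent 0. Circular
  statistics were chosen over a linear SD because hue wraps; the angular
  deviation lives in `[0, sqrt(2)] ~ [0, 1.41]`, consistent with observed
  natural-scene magnitudes around 0.8-1.1.
* **Saturation and brightness mean / SD** (3-6). Plain arithmetic means and
  population standard deviations of the saturation and value planes.
  Objective brightness is computed but flagged
  `brightness_unreliable`: in ecological photographs apparent brightness is
  dominated by camera exposure and time of day, and the analysis designs
  exclude it by default.
* **Green and blue pixel ratio** (7-8). Fraction of all pixels with hue in
  a band (defaults: green `[70°, 170°)`, blue `[170°, 260°)`) and enough
  chroma (saturation ≥ 0.15, value ≥ 0.10) to be a color at all.
* **Sky pixel ratio** (9). Computed on a *companion image* in which
  everything that is not sky has been blackened (by hand in real studies;
  by construction in the generator). Sky = blue-band pixels plus grey/white
  pixels (saturation ≤ 0.15, value ≥ 0.55, for overcast sky), never
  mask-black pixels (value < 0.02); the denominator is all pixels. The
  package deliberately performs no automatic sky segmentation.
* **Edge densities** (10-12). A Canny detector (Gaussian σ = 1.4, Sobel
  gradients, non-maximum suppression, hysteresis) marks edge pixels;
  overall edge density is their fraction of all pixels. A Hough line
  detector splits edge pixels into *straight* (supporting a detected line
  segment) and *non-straight* (everything else). The split is a strict
  partition, so straight + non-straight = overall *exactly*. Reported
  values for the same image set elsewhere do not always satisfy this
  identity, which suggests overlap conventions differ between
  implementations; this package enforces the partition because it makes
  the three numbers mutually interpretable.
* **Entropy** (13). Shannon entropy of the 256-bin histogram of the BT.601
  luma plane, in bits: 0 for a constant image, 8 for an exactly uniform
  histogram.
* **Fractal dimension** (14). The luma plane is binarized at the Otsu
  threshold (foreground defaults to the dark class — structure against
  bright sky) and the box-counting dimension is the negated least-squares
  slope of `log N(s)` against `log s` over the dyadic sizes
  `2, 4, ..., floor(min(H, W)/4)`. A filled region approaches 2, a thin
  line 1; estimates outside `[1, 2]` are flagged. A single origin-anchored
  grid is used; a multi-offset minimum-count mode is not provided because
  on the dyadic ladder it changes estimates by less than the fit noise.

Per participant, features are averaged across all their window images —
circularly for mean hue — giving one value per feature per person.

### Numerical choices in the edge detector

Two conventions here are genuinely open and worth recording:

* **Hysteresis thresholds are absolute.** Thresholds (defaults 0.10/0.20)
  are fractions of the detector cascade's own response to a full
  black-to-white step, measured with the same smoothing. Thresholds
  relative to the *observed* maximum gradient would make any noisy but
  featureless image produce edges; absolute thresholds let it produce
  none, and make "edge" mean "local contrast above 10%/20%" independent of
  σ.
* **Straight means a long contiguous segment.** An edge pixel is straight
  if it lies within 1 px of a Hough-detected line *and* belongs to a
  contiguous run (gaps ≤ 1.5 px along the line) at least 10% of the image
  diagonal long. The minimum length is the discriminating parameter: a
  circular arc of radius `R` stays within tolerance `t` of a chord for
  only about `sqrt(8 R t)` pixels, so short minimum lengths classify any
  gently curved contour as straight. The default was calibrated on the two
  generator archetypes before the test suite was frozen: rectilinear
  scenes yield straight-to-overall ratios around 0.6-0.7, foliage scenes
  around 0.3, a circle outline exactly 0, and full-length lines exactly 1.
  Gaps are *not* bridged beyond 1.5 px because fragmented (dashed)
  contours are conventionally counted as non-straight.

## Behavioral outcomes

**State negative affect.** Twenty state items (facets: emotionality,
worry, euthymia, dysthymia; five each) answered 1-4. Euthymia items are
reversed (`5 - r`), then all items are summed: the composite spans 20-80,
higher = more negative affect.

**Delay discounting.** Each of seven delays (6 h to 5 years) is one
staircase block: the opening trial offers EUR 50 now against EUR 100
delayed, and each choice halves the remaining step — the adjustment after
trial `t` is `100 / 2^(t+1)` EUR (±25, ±12.5, ...). The indifference point
of a block is the offer a hypothetical seventh trial would present (the
titration limit), so six choices pin it to within 0.78 EUR. The AUC
normalizes delays by 1825 days and indifference points by 100 EUR,
anchors the curve at (0, 1) — a delayed euro is worth a euro at zero
delay — and accumulates trapezoids; the anchor can be disabled
(`anchor = FALSE`) since published AUC conventions differ on it. Larger
AUC = less impulsive choice.

## Inference

All associations are tie-corrected Spearman correlations with two-sided
p-values from the `t` approximation on `n - 2` df. Models are OLS with
standardized betas (`B * sd(x) / sd(y)`) and the full Gaussian-likelihood
AIC (`stats::AIC`). Selection is bidirectional stepwise: from the
forced-only model, repeatedly apply the single addition or deletion that
most lowers AIC, never dropping forced terms, stopping at a local minimum;
ties (within 1e-8) prefer the smaller model, then the earlier-listed
candidate. Because the AIC constant cancels in comparisons, the selected
model is invariant to it, but printed AIC values are only comparable
within one convention.

Two designs are provided. **Design A** (view ratings): per criterion
(perceived % nature, % man-made, view quality), stage 1 selects among the
12 usable LLVFs; stage 2 forces the stage-1 terms and lets seven
sociodemographic controls compete, probing confounder robustness.
**Design B** (outcomes): per outcome (negative affect, AUC), seven
controls are forced — confounders stay in the model regardless of
significance — and the subjective ratings plus the 12 LLVFs compete in
block 2. The sky percentage is withheld from candidate sets because the
three composition shares sum to 100 and would be collinear. Exclusions
follow the cohort design: the single diverse-sex participant is removed
(a one-person factor level would distort the fit), then listwise deletion
per outcome; sex is afterwards encoded female = 1, income as the ordinal
band index 1-7. Significance is α = 0.05 two-sided, with no
multiple-testing correction — the designs are exploratory, and the
selective-inference optimism of stepwise p-values is a known, accepted
limitation here.

## What the generator emulates, and what it does not

Scenes are *schematic*: a sky band (blue gradient or overcast grey), a
background wall, rectilinear buildings with large window panes, and
foliage placed on the highest values of midpoint-displacement noise
(persistence 0.8, chosen so foliage outlines are ragged at the pixel
scale like leaf texture). Schematic rendering is a deliberate design: the
extractor consumes pixel statistics, not semantics, and only schematic
scenes make every ground-truth area fraction exact (foliage pixels are
selected to hit the target count to within one pixel). Default scenes are
96 × 96 px, which keeps the dyadic box-count ladder at four sizes and a
full cohort extraction within a few minutes on one core.

The default cohort reproduces the study conditions the package targets:
110 participants, image counts from a min-1-truncated negative binomial
with mean 5.58 and SD 4.01 (truncation shifts these moments slightly;
this is documented rather than re-calibrated), demographics drawn
independently from the published marginal bands (no copula — the joint
structure is not reported), exactly one diverse-sex participant, and
injected missingness (2 inventory, 1 choice log) so the exclusion
bookkeeping (110 → 109 → 107) is exercised. Ratings come from planted
linear models on true scene fractions: the composition triple is
logistic-normal noise (SD 0.35) around the truth, rounded by largest
remainder so it sums to exactly 100. Negative affect is planted on the
brightness rating with coefficient −0.15 (SD 6), i.e. a standardized
effect near −0.3; discount rates are log-normal (`meanlog log(0.02)`,
`sdlog 1.2`), spanning near-patient to steeply discounting agents, and
choices come from a hyperbolic agent (`choose delayed iff
100/(1 + k D) ≥ offer`; ties break toward delayed, a convention the task
itself cannot identify).

What the generator does **not** emulate: photographic texture, lighting
and camera variation (so passing tests say nothing about robustness to
exposure differences — indeed objective brightness is excluded for
exactly that reason), ephemeral content (clouds, birds, people),
perspective and window-frame artifacts (masks and cropping are assumed
done upstream), and any dependence of discount rates on the view (AUC is
generated independent of scene truth; its model estimates a null).

## Degenerate inputs and edge cases

* All-achromatic images: hue statistics are `NA` + flag, never 0.
* Constant images: entropy 0, empty edge map, binarization degenerate →
  FD is `NA` + flag; images under 32 px on a side cannot support three box
  sizes and raise an error.
* Missing sky mask: `sky_ratio` is `NA` and flagged; the pipeline warns
  and continues.
* Zero-variance outcomes and rank-deficient designs raise errors naming
  the offending columns.
* Determinism: every random step derives its seed from the master seed
  and a stage label (`stage_seed`), so reruns are byte-identical and
  stages can be rerun independently.

## Problem sizes used in validation

The package's own validation (test suite and acceptance checks) runs the
full default cohort (110 participants, ~600 images at 96 × 96), 200
replicates of a planted two-predictor selection problem at n = 109 with
12 candidates, exhaustive best-subset cross-checks up to 6 candidates,
and brute-force box-count equivalence on images up to 64 × 64. These
sizes were chosen to mirror the cohort scale the package targets while
keeping a complete validation run within minutes on a single core.

## Known limitations

* Edge and fractal features are resolution-dependent; comparisons across
  cameras should use the optional `resize_max` normalization.
* The Hough split's minimum segment length scales with the image
  diagonal, which is a convention, not a law; at very high resolutions a
  fixed metric length would be preferable.
* AIC-stepwise is liberal: under the null it admits spurious candidates
  at a non-trivial rate (the recovery tests bound false positives on
  average, not per run), and post-selection p-values are optimistic.
* The generator's demographic margins are independent; any analysis of
  demographic joint structure is outside its fidelity.
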