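---
title: "Methods: composition quantification and elastography staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composition quantification and elastography staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpia)
```

This vignette records the model behind `qpia`, the choices that were
genuinely open when the package was designed, and what its tests do and
do not establish.

## 1. Composition model

An HE-stained thrombus cross-section contains three color families with
a biological reading: red (red blood cells and platelet trabecula), pink
(fibrin) and blue (nuclei plus calcium salt deposition, which the stain
cannot separate — neither does this package). Quantification runs over a
binary ROI mask supplied alongside the image; delineation itself is out
of scope.

**Background gate.** A pixel is background (lumen, white space, slide)
when it is both bright and unsaturated: `max(R,G,B) > b0` and
`(max - min)/max < s0`. Defaults `b0 = 230`, `s0 = 0.12`. Background
pixels are excluded from the denominator: the reported fractions
describe tissue composition, not the vessel lumen.

**Classifier.** Remaining in-ROI pixels take the label of the nearest
reference color in RGB Euclidean distance. Defaults: red (150, 30, 40),
pink (230, 160, 180), blue (70, 60, 140) — typical HE hues, exercised
only through synthetic data and fully configurable. This is the simplest
reproducible reading of "isolating the red, pink and blue components";
stain-vector deconvolution or learned segmentation would be defensible
alternatives but are deliberately out of scope (they would make the
planted-truth tests circular). Distance ties are broken by the fixed
class order red < pink < blue, for determinism only.

**Red weighting.** The red content parameter is not a raw pixel count:
each red pixel contributes

$$w(f_\mathrm{red}) = \left(\max\!\left(0,
  \frac{f_\mathrm{red} - f_0}{1 - f_0}\right)\right)^{\gamma},
  \qquad f_\mathrm{red} = \frac{R}{R+G+B},$$

with defaults `f0 = 1/3` (the achromatic value: any gray pixel has
`f_red = 1/3`) and `gamma = 2`. The exact nonlinear weighting used in
the original QPIA literature is not published; this thresholded power
law is a declared stand-in with the right boundary behavior
(`w(f0) = 0`, `w(1) = 1`, monotone), not a reconstruction. `gamma = 0`
recovers unweighted counting and is the recommended sensitivity check.
Whether pink should also be intensity-weighted is unknown; pink and blue
carry unit mass here.

**Remainder rule.** `Rb = 1 - Rr - Rp` by definition, so the triple sums
to 1 exactly. Internally the remainder is computed as `1 - (Rr + Rp)`
(note the association) and a sub-tolerance float overshoot of `Rr + Rp`
above 1 is clamped, which makes the sum *bit-exact*, not merely close —
the conservation tests assert `sum == 1` with `identical()`.

## 2. Staging model

**Series.** Replicate Emean values (the device protocol takes three) are
collapsed by their mean per animal-day; the per-day series value is the
mean across animals, with the across-animal sample SD attached when at
least two animals contribute. Missing days stay missing — nothing is
imputed. The whole-thrombus value on a day is the mean of head, body and
tail (rounded to 2 decimals for Young's modulus, matching the reporting
precision used throughout).

**Transition detection.** The staging question — on which days does the
trend change slope — is answered by model selection, not hypothesis
testing: for every admissible ordered pair of interior changepoint days
(each of the three segments keeping at least `min_seg = 2` points), a
*continuous* piecewise-linear model is fitted by least squares (hinge
basis `1, d, (d-d1)+, (d-d2)+`), and the pair with minimal SSE wins.
A changepoint is the last day of its segment. With 14 days there are 45
candidates, so exhaustive search is exact and fast, and an independent
enumeration (knot-value basis, normal equations) is used as the test
oracle. Ties — e.g. a perfectly linear series, where every candidate
fits equally well — resolve to the lexicographically smallest pair; the
tie tolerance is relative (`1e-9`), so float dust cannot flip the
winner. Changepoint days are invariant under affine rescaling of the
values (kPa vs Pa).

Nothing here is a significance test, and no multiple-testing machinery
is attached: the fitted days are a deterministic reconstruction of where
a three-stage description fits best.

**Reversal detection.** Recanalization refills the clot with fresh red
cells, reversing the late decline of Rr. The rule: the first day
`d >= window_start` (default 8, just after the late transition) with two
consecutive rises, `v(d) > v(d-1)` and `v(d+1) > v(d)`. Two rises are
required so a single noisy day cannot trigger; the cost is that a
reversal on the last study day is undetectable — accepted, since the
observed reversals fall on days 9–11 of 14.

**Heterogeneity.** Sample SD with the `n - 1` denominator everywhere
(groups are tiny: 3 parts, 3 animals). Within-thrombus: SD across the
three parts of one animal-day. Between-thrombus: SD across animals for
one day/part; it requires at least two animals and is omitted (with a
logged notice) for single-animal runs rather than reported as 0.

## 3. The synthetic world

The generators are first-class, tested code; their defaults *are* the
stated study conditions, chosen once:

* **Elasticity endpoints** (day 1 → day 14, kPa): head 2.01 → 13.29,
  body 3.27 → 15.91, tail 1.79 → 10.51, whole 2.36 → 13.24 — the printed
  per-part ranges.
* **Changepoints** default to days (4, 7); the rise is split 10% / 55% /
  35% across the three segments, which with (4, 7) yields the observed
  low/high/medium slope ordering.
* **Noise** grows with day: SD `noise_sd0 * (1 + noise_growth*(d-1))`,
  defaults 0.3 kPa and 0.35/day, giving a day-14 SD near 1.7 kPa — the
  magnitude of the printed late-stage deviations. Composition noise
  defaults to 0.02 (fraction units) with growth 0.15, applied on the
  simplex (perturb, clip at 0, renormalize, remainder rule).
* **Composition** declines from Rr = 0.96 (the documented day-2 mean is
  0.9513) to a floor of 0.45 (near the documented day-11 head/body
  values), splits the complement 0.8/0.2 between pink and blue (the
  approximate pink share across the documented rows), bottoms out the
  day before the planted reversal (head 9, tail 10, body 11) and then
  rises at 0.02/day. Day-by-day values between the documented anchor
  days are interpolations, and the cohort manifest flags them as such.
* **Images**: a Gaussian random field smoothed at `blob_scale` (default
  8 px) is split by in-ROI quantiles into red/pink/blue/background in
  the target proportions — giving interleaved blob-shaped regions rather
  than geometric shapes — then painted with the palette reference colors
  plus per-channel Gaussian noise (default SD 12 of 255, a realistic
  stain/scanner variability). The ROI is the inscribed ellipse. Quantile
  assignment makes the planted areas exact to one pixel, far inside the
  0.5% tolerance. Default target fractions (0.55, 0.27, 0.08) leave 10%
  of the ROI as lumen-like background.

Every generator is driven by one explicitly seeded RNG stream and
restores the caller's RNG state; identical spec + seed gives
bitwise-identical artifacts. Cohorts derive per-animal seeds from the
master seed and record *all* planted truths in `manifest.json`.

**What a green test does not establish.** The synthetic images are
palette colors plus white noise: classification on them is nearly
perfect by construction, so the recovery tests validate the *bookkeeping*
(masking, weighting, remainder arithmetic, determinism), not the
classifier's adequacy on real scanner output with stain variation,
compression artifacts or out-of-palette hues. Likewise the planted
series are exactly piecewise-linear; real trends are not, and the fitted
changepoint days on real data inherit that approximation.

## 4. Numerical and interface choices

* Pixel coordinates are 0-based/row-major in reports; masks are
  same-shape rasters. RGBA alpha is dropped; fully transparent pixels
  become white background.
* PNG I/O uses the png package; TIFF support is a minimal baseline codec
  (uncompressed, chunky, 8-bit RGB) written here because no TIFF reader
  exists in the dependency set — anything outside that subset raises a
  format error naming the offending property (bit depth, compression,
  samples per pixel). It was cross-validated against an independent
  reference reader during development.
* Percentages are reported to 2 decimals, the precision of the study
  tables; JSON reports have stable key order and embed the resolved
  configuration and package version.
* Degenerate inputs fail loudly with classed conditions (validation /
  I/O / invariant), mapped by the CLI to exit codes 2/3/4: empty ROI,
  all-background ROI (no tissue), sum-to-one violations beyond 1e-9,
  series too short or gapped for fitting, fewer than 2 animals for
  between-thrombus SD.
* Scanner magnification is never stated for this class of data, so
  resolution metadata is optional and unused by computation.

## 5. Known limitations

Rb aggregates nuclei and calcium without sub-classification. The QPIA of
a recanalizing vessel counts everything inside the ROI, including fresh
refill — late-stage fractions describe vessel content, not the original
clot. The elasticity and composition generators share a changepoint
parameterization but are independent draws, not a joint biophysical
model. The CLI's `quantify` treats each image in isolation; batch
orchestration is left to the caller.
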