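---
title: "Measuring infarct, edema and BBB disruption in one set of brain slices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring infarct, edema and BBB disruption in one set of brain slices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triquant)
```

## The measurement problem

After middle cerebral artery occlusion (MCAO) in the rat, three read-outs
characterize the injury: the infarcted volume, the hemispheric edema, and
the permeability of the blood-brain barrier (BBB). Classically each
read-out consumes its own set of brains — TTC staining for infarct, wet
hemispheric volumes for edema, and fluorometric Evans blue (EB)
quantification for BBB — because the stains interfere: EB-laden tissue
scans dark and is mistaken for viable (TTC-red) tissue by a luminance
threshold. `triquant` implements a combined single-brain protocol in which
all three quantities come from the same six 2 mm coronal slices, with a
blue channel-mixer filter neutralizing the EB interference before infarct
thresholding.

## The image pipeline

Each slice scan passes through five steps (`measure_slice()`):

1. **Tissue segmentation.** A pixel is tissue when its max-channel
   distance from the declared background color (white by default) exceeds
   `tolerance` (default 30/255). Components smaller than `min_object_px`
   (default 64 px) are debris; holes are filled so that pale infarcted
   cores stay inside the mask.
2. **Hemisphere split.** A vertical midline through the tissue centroid
   column; `orientation` maps image sides to anatomical sides, and an
   explicit `midline` can override the centroid. The centroid is adequate
   for well-oriented scans and phantoms: with up to 15 % unilateral
   swelling the centroid shifts by a few pixels but stays inside the
   inter-hemispheric gap.
3. **Blue detection** on the *unfiltered* RGB image: a tissue pixel is
   EB-stained when `(B - max(R, G))/255 > blue_margin` (default 30/255).
   The rule is hue-free and monotone in stain intensity.
4. **Blue filtering.** The channel mixer replaces each pixel by
   `clamp(c_R R + c_G G + c_B B, 0, 255)/255`. The default coefficients
   `(0, 0, 1)` keep only the blue channel: EB (high blue) maps bright,
   like unstained pale infarct, and TTC-red viable tissue maps dark. The
   original protocol names the channel-mixer tool but not its settings;
   `(0, 0, 1)` is the simplest setting that reproduces the reported
   effect, and it is exposed as configuration rather than hard-coded.
5. **Infarct thresholding.** Otsu's method on the within-tissue histogram
   (256 bins, lowest-cut tie-break), classifying bright pixels as infarct.
   A `fixed` level is available as an override.

Infarct pixels are counted over the whole tissue (not per hemisphere),
matching the convention that unstained area *is* infarct once the filter
has removed the dye. Blue pixels are attributed to the ipsilateral (right,
for right-sided MCAO) hemisphere by default; `blue_scope = "slice"`
counts them over the whole slice instead — the source protocol does not
state which was used, and the difference vanishes when extravasation is
confined to the occluded side.

### Degenerate histograms

Otsu's criterion always returns *some* cut, including on a unimodal
histogram, where it simply bisects the noise of healthy tissue and would
report roughly half of a sham brain as infarcted. Two guards apply
(`classify_infarct()`):

* a single gray level within tissue → zero infarct, slice flagged;
* a successful cut whose two class means differ by less than
  `min_contrast` (default 0.25 on the 0–1 gray scale) → zero infarct,
  slice flagged.

The default of 0.25 sits far above the noise width of a uniform region
(about 0.02 at scanner-like noise) and far below the viable-to-pale
contrast after blue filtering (about 0.65 with the default phantom
palette), so the guard is insensitive to its exact value over a wide
range.

## The three formulas

With `L` and `R` the summed left/right hemisphere areas over the slice
set (areas in pixels; equal slice thickness makes sums volume proxies),
`I` the summed infarct area and `B` the summed blue area:

* **Infarct volume**, swelling-corrected:
  `corrected = I x L / R`, reported as `100 * corrected / (L + R)`
  (`normalization = "total_brain"`) or `100 * corrected / (2 L)`
  (`"contralateral"`). Both are offered because the source protocol
  describes the first and reports group data as percent of the
  contralateral hemisphere; the two differ only through the edema term.
* **Edema** (Kaplan): `100 * (R - L) / L`, negative when the ipsilateral
  hemisphere shrinks.
* **Image-based BBB disruption**: `100 * (L - (R - B)) / L`. Note the
  edema coupling: with `B = 0` this is exactly minus the edema ratio, and
  swelling can offset a genuine dye area. This is a property of the
  formula, preserved deliberately.

`adc_lesion_percent()` applies the same corrected-percent computation to
an apparent-diffusion-coefficient map thresholded at 0.53e-3 mm²/s, so
the ratio formulas can be reused on MRI-derived volumes.

## Fluorometry

`fit_standard_curve()` is an unweighted OLS line of fluorescence on
concentration (ng/mL); the blank is an ordinary point and the intercept is
free. Standards are specified as ng per 200 µL well, the usual 0–2000 ng
series. The curve's validity window is the observed standards range —
that is what the `"error"` extrapolation policy can defend — rather than
a fixed 10–500 ng/mL window; readings below the intercept clamp to zero
under the default policy.

`extravasation_index()` inverts the curve on the diluted supernatant read
and rescales: `index = conc x dilution x volume / weight` (ng/g). The
default `dilution_factor = 4` reads the "1:3 with ethanol" bench step as
1 volume supernatant + 3 volumes ethanol; laboratories that read 1:3 as a
final factor of 3 should set the factor explicitly, since it scales every
index linearly.

`interference_assay()` reproduces the TTC-interference design: paired
readings per TTC concentration against a 0 % baseline, percent-of-baseline
per pair, two-sided Wilcoxon signed-rank (exact for small n without ties).
The baseline row normalizes each replicate against the baseline mean, so
it reports mean 100 with a nonzero SEM, as replicate tables conventionally
do.

## Statistical routing

`compare_groups()` uses Welch's t-test (with Cohen's d) only when both
groups pass a Lilliefors-corrected Kolmogorov–Smirnov normality check at
the 0.05 level *and* both have n ≥ 8; otherwise the two-sided
Mann–Whitney U with rank-biserial r. The Lilliefors form is used because
a normality "check" against a fully specified normal is almost never what
is meant; groups below n = 5 cannot be tested and route non-parametric.
`correlate()` uses Pearson only under normality and n > 30 (interval
scale is asserted by the caller), otherwise Spearman. The t-test variant
is Welch throughout: the protocols being compared have no variance-equality
guarantee.

## What the phantoms emulate — and what they do not

`generate_brain()` renders each slice as two mirrored ellipses on a white
canvas (160 x 120 px by default, semi-axes tapering over the six slices),
the right ellipse inflated by `swelling_factor`, with a lateral angular
wedge of the right ellipse painted pale (infarct) and an inner portion of
the wedge (a fraction `eb_fraction` of its area) overpainted dark blue.
The wedge is a parametric sector, so its painted area tracks
`infarct_fraction` exactly up to rasterization; ground-truth counts are
recorded before i.i.d. Gaussian channel noise (sd 6 by default) is added.
Default colors are deep TTC red (190, 40, 40), pale cream (240, 228, 205)
and dark EB blue (45, 45, 170) — qualitative matches to double-stained
slices, configurable since no colorimetry is published. The cream value
keeps the infarct comfortably above the background tolerance; a near-white
infarct color would sit on the segmentation boundary by construction.

The phantoms deliberately omit: scanner vignetting and JPEG artifacts,
slice deformation and inter-slice shape continuity, EB extending beyond
the infarct, partial-intensity staining gradients, and any anatomical
realism (the wedge mimics an MCA cortical territory only in spirit).
Passing recovery tests therefore demonstrates that the *computation* is
faithful — segmentation, splitting, thresholding and the formulas — not
that the pipeline is robust to every real-scan artifact. In particular,
when extravasation extends beyond the infarct the blue filter will count
those pixels as infarct; this is documented behavior, not corrected.

## Validation problem sizes

The shipped validation (test suite and `scripts/acceptance.R`) uses: 20
randomized integer area tables for formula exactness; 20 phantoms with EB
covering 50–100 % of the infarct for filter invariance (filtered error
under 1.5 percentage points, unfiltered underestimate over 25 %); a
30-phantom sweep of infarct fraction 0–14 % and swelling 1.00–1.15
(recovery slope within [0.9, 1.1], r > 0.95, edema within 2 pp); a
12-point EB sweep for image-vs-truth BBB concordance (r > 0.9); 20-sample
plates (exact recovery noiseless, < 5 % mean error at 1 % read noise, the
noise referenced to the maximum sample signal); and 500/200 simulated
assays for Wilcoxon type-I (0.05 ± 0.02) and power against a 50 %
multiplicative effect (> 0.9 at 10 pairs). These sizes reproduce the
study conditions at desk scale; all are seeded.

## Known limitations

* The centroid midline assumes roughly symmetric placement; badly tilted
  scans need an explicit `midline` or pre-rotation.
* The `(0, 0, 1)` channel-mixer setting reproduces the qualitative
  blue-removal effect but cannot be verified against the original
  software settings, which were not published.
* The BBB image formula's edema coupling means the brain-level percentage
  can be zero despite visible dye when swelling compensates; per-slice
  values (`bbb_image_percent(..., per_slice = TRUE)`) help diagnose this.
* Fluorometric indices are per gram wet tissue; no protein normalization
  is attempted.
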