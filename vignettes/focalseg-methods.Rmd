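---
title: "Map-algebra segmentation of fluorescence microscopy images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Map-algebra segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focalseg)
```

## The problem

Semi-quantitative analysis of fluorescently tagged drug uptake in tissue
reduces, in practice, to one number per image: the mean pixel intensity of a
region of interest (RoI), typically the cytoplasm of one cell type.
Confocal images of vascularized tissue such as the stria vascularis are
*tripartite* in intensity: a dim, homogeneous background; a heterogeneous
mid-intensity parenchyma (the RoI); and brightly stained, often saturated,
branching blood vessels.  Manual segmentation with digital erasers is the
traditional gold standard but is slow and biased toward high variance.
`focalseg` implements supervised machine segmentation for this image class:
the user chooses a method and parameters and inspects the outputs; the
pixel-level work is automated.

All methods share one mechanism, borrowed from map algebra as used in
geographic information systems.  The image is a raster with per-pixel
coordinates; a *masking image* ("sketchpad") on the same coordinates holds
computed values — by default a focal (neighborhood) mean, optionally a
local Moran autocorrelation field; thresholds are computed from the
*original* image and applied to the *mask*, and pixels whose mask value
falls inside the threshold interval are retained with their original
intensities.  Selecting through a smoothed mask discounts isolated pixels
that disagree with their neighborhood, which is what makes the
segmentation's articulation smooth rather than speckled.

## Data model

A `raster_image` is a matrix of intensities normalized to [0, 1] plus a
logical validity matrix.  Validity, not a zero intensity, encodes "removed"
(gross segmentation zeroes excluded regions on disk; on import, exact zeros
are flagged invalid by default so that removed pixels never masquerade as
dark ones — a switch restores whole-image counting where bin arithmetic
over all pixels is wanted).  Focal operations mark a border frame of
`floor(kernel_size / 2)` pixels indeterminate, since a centered kernel
extends past the image edge there; neighborhood statistics are computed
over valid pixels only, so gross-segmentation boundaries do not erode the
RoI by a kernel width.

## The four methods

**Percentile** (default; parameters `low_pct = 20`, `high_pct = 70`,
`smooth_kernel = 7`).  Thresholds are the 20th and 70th percentile
intensities of the original image — type-1 empirical quantiles, the
smallest order statistic with at least p% of pixels at or below it, with no
interpolation — applied to the 7×7 focal-mean mask.  Percentiles are
nearly invariant pointers: across images whose brightness varies by almost
a factor of three, the *intensity* thresholds move widely while the
*percentile* thresholds, and the retained fraction, barely move.  This is
the method the validation battery leans on.

**First difference** (`offset = 0.07`).  The integrated intensity is the
cumulative sum over the 100 histogram bins of (bin frequency × bin
midpoint); its first difference peaks at the predominant (cytoplasmic)
band.  The optimum is the interior global maximum of the first difference —
the point where the curve "turns over" — and the thresholds sit a fixed
offset of 0.07 (normalized units) to either side, assuming rough symmetry
of the band.  A monotone first difference has no optimum and the method
refuses, by design, rather than guessing.

**Second difference** (same offset).  The downward root crossing of the
second difference coincides with the first-difference optimum; the first
ascending crossing after it estimates the upper threshold.  The tail of the
curve is asymptotic and noisy, so ascending crossings followed by `run = 5`
bins flatter than a tolerance are terminated.  Two numerical choices
matter here.  First, the flatness tolerance adapts to the curve (2% of the
peak first difference, floored at 1e-4): counting noise in the tail scales
with histogram mass, and a fixed absolute tolerance either passes noise or
swallows signal depending on image size.  Second, when *every* ascending
crossing is terminated — on a clean profile the second difference descends
monotonically into the empty valley above the band, and a threshold at the
valley would admit bright vessel-edge pixels through the smoothed mask —
the method falls back to an inflection estimate, the first local minimum of
the second difference after the downward crossing.  For a roughly Gaussian
band this is one standard deviation above the center.  The lower threshold
reuses the first-difference offset below the downward crossing; no closed
rule exists for it, and this heuristic is deliberately simple.

**Local Moran** (`moran_cutoff = 0.4`, `moran_kernel = 7`).  The mask is
the local Moran autocorrelation field:
$I_i = \frac{x_i - \mu}{m_2}\cdot\frac{1}{|N_i|}\sum_{j\in N_i}(x_j - \mu)$,
with global mean $\mu$ and population variance $m_2$ over valid pixels, and
$N_i$ the valid window neighbors excluding the center.  Averaging (not
summing) neighbor deviations keeps the statistic comparable across kernel
sizes.  Both the dim background and the saturated vessels are homogeneous
*and* far from the global mean, so both score high; the heterogeneous
cytoplasm scores near zero.  One cutoff therefore separates the RoI from
both flanking regions: the acceptance interval runs from the lowest Moran
value up to 0.4.  This is the only method whose thresholds live in mask
units rather than intensity units.

Thresholds are inclusive at both ends (ties at a percentile boundary are
all retained — "at or below the 20th percentile" implies inclusivity at the
low end, and the high end is treated symmetrically).  Every method is
deterministic given the image and configuration, and every result records
its thresholds, configuration, and summary statistics (mean, sample
standard deviation, count, moment skewness) of the retained pixels.

## Histogram-space machinery

Two views of the same multiset of intensities drive the methods.  The
*intensity profile* is the fixed 100-bin histogram and its integrated
vector (100 values), first difference (99), and second difference (98);
bin midpoints represent bins because midpoints minimize quantization bias
and make the conservation identity — final integrated value equals the mean
of midpoint-quantized intensities — exactly testable.  The *percentile
curve* is the inverse empirical distribution function, and its first
difference `delta[p] = q[p+1] − q[p]` (the intensity step bought by one
percentile point) exposes structure: small even steps across the
heterogeneous RoI, upward inflections at its edges.  `find_plateau()`
locates the longest run of steps no larger than twice the mode of the
3-decimal-rounded `delta` values (ties resolve to the smallest candidate)
and reports its endpoints as candidate thresholds.  This is a diagnostic
aid for supervision; production percentile segmentation uses the fixed
20/70 percentiles.

## The synthetic generator

No real confocal data ship with the package; a seeded generator produces
tripartite images with per-pixel ground truth (excluded / background /
cytoplasm / vessel), and the ground-truth cytoplasm label serves as the
*manual-segmentation surrogate* in all manual-versus-machine comparisons
(reports label it as a surrogate).  Defaults: 256×256 pixels; background
N(0.05, 0.01); cytoplasm N(0.45, 0.08) with spatially correlated texture
(white noise box-smoothed over a 4-pixel correlation length, then
re-standardized — the simplest mechanism giving the local-autocorrelation
contrast the Moran method needs); three vessel ridges 8 px wide at
N(0.95, 0.02), drawn as biased random walks spanning about 70% of the
cell-layer band with one bifurcation per walk at probability 0.5; a zeroed
gross-segmentation band over 10% of the width; and a global
`brightness_scale` multiplier for dim/medium/bright sweeps, with clipping
at 1 (a 1.4× sweep saturates vessels, as real acquisition does).

Free geometry parameters not dictated by the intensity model were fixed
once for morphological plausibility: thin wavy background margins of about
2% of the image height at the top and bottom edges (the strial cell layer
fills most of a well-framed field), and the 70% vessel span.  Under these
conditions the raw valid-pixel distribution is right-skewed (skewness
≈ 0.8–0.9, dominated by the bright-vessel tail) while the cytoplasm alone
is symmetric — giving histogram-reshaping diagnostics something real to
detect.  Z-stacks share the base seed's geometry; slice *k* shifts the
cytoplasm mean by (k−1)·`drift_per_slice`, drifts vessel paths laterally by
a cumulative random walk scaled to the same drift, and draws fresh noise
from a seed derived as `seed + k`.

The generator does **not** emulate optics: no point-spread blur across
region boundaries, no photon shot noise, no depth attenuation, no
uneven illumination.  Passing tests on synthetic images therefore
demonstrate the algorithms' internal correctness and their robustness to
intensity arithmetic, brightness, and stack drift — not performance on
real tissue, where boundary blur and illumination gradients can move
thresholds in ways these images cannot exhibit.

## Validation battery

*Perturbation tests*: add a constant (0.196) to, or multiply by a factor
(0.8, 1.25), every valid pixel, re-segment with the same configuration, and
compare the observed segmented mean with the transformed baseline.
Thresholds are deliberately recomputed on the perturbed image — percentile
thresholds are image-relative, so freezing them would test cutoffs, not the
method.  For unclipped additive shifts the percentile method's retained
pixel *set* is provably identical (order statistics and the mask shift
together), so the mean tracks exactly; the battery asserts the weaker 1.5%
bound as stated and the exact set identity separately.  Reports carry two
clipping fractions: over all valid pixels (saturated vessels necessarily
clip under a positive shift) and over the baseline retained set, which is
what the expected-mean arithmetic concerns; tests require the latter under
1%.

*Trend comparison*: cosine similarity, mean percentage offset, per-set
standard deviations, and a two-sided paired t-test p-value (reported, not
judged) between surrogate-manual and machine means across an image suite.
On the default 20-image suite the cosine similarity exceeds 0.999 with the
machine means a consistent ~2% low and less dispersed — machine
segmentation selects by intensity, so it trims the tails that a
morphology-driven reference keeps.

*Stack consistency*: maximum adjacent-slice change in retained mean and
count.  Percentile segmentation tracks the generator's drift smoothly; the
first-difference method occasionally jumps dramatically when the bin-
quantized optimum, or a competing bright-vessel peak in the first
difference, captures the search — the same instability that motivates
preferring percentile methods for stacks.

*Distribution diagnostics*: raw-versus-segmented skewness and 100-bin
histograms; all four methods reshape the skewed raw distribution toward an
approximately normal retained one.

## Problem sizes and runtime

The test suite and the acceptance script run on 256×256 images (the
generator's default; every size-dependent quantity is parameterized), with
suites of 5–20 images, 10-slice stacks, one 1024×1024 image for
whole-image bin arithmetic, and exhaustive brute-force oracle comparisons
on grids up to 16×16.  The full suite completes in well under a minute on
one core.

## Known limitations

- The first- and second-difference methods assume the RoI owns the
  dominant first-difference peak; on images whose vessel load is unusually
  high the bright peak can win, and supervision (inspecting thresholds
  against the histogram) is the intended guard.
- The Moran cutoff discriminates within a narrow window, as the gap
  between cytoplasm and background/vessel autocorrelation shrinks with
  texture correlation length; 0.4 suits the default contrast.
- Multi-channel and volumetric (3-D kernel) segmentation are out of scope;
  stacks are processed slice-wise.
- `find_plateau()`'s mode-referenced rule needs a few repeated rounded
  delta values; on extremely dim images (steps below 0.0005) the reference
  degenerates and the function refuses rather than guessing.
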