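# focalseg

Supervised, automated segmentation of single-channel fluorescence
microscopy images, for semi-quantitative pixel-intensity analysis of cell
cytoplasm in tripartite tissue images: a dim homogeneous background, a
heterogeneous mid-intensity parenchyma (the region of interest, RoI), and
brightly stained branching blood vessels.  The motivating application is
measuring fluorescently tagged drug uptake in the intermediate-cell layer
of the stria vascularis, where manual segmentation of the vasculature with
digital erasers is slow and biased toward high variance.

## The approach

Every method uses map algebra: the image is a raster grid, and a
coregistered **masking image** holds computed per-pixel values — a focal
(neighborhood) mean by default, or a local Moran autocorrelation field.
Thresholds are computed from the **original** image and applied to the
**mask**; pixels whose mask value falls in the interval are retained with
their original intensities.  Four threshold rules are provided:

- **percentile** — thresholds at fixed empirical quantiles of the RoI
  (defaults: 20th and 70th percentile, 7×7 mean smoothing).  Percentiles
  are nearly invariant pointers across image brightness, which makes this
  the most robust method.
- **first difference** — the integrated intensity
  `I_k = Σ_{b≤k} f_b · x_b` over 100 histogram bins has a first
  difference that peaks at the cytoplasmic band; thresholds sit a fixed
  offset (default 0.07) to either side of that optimum.
- **second difference** — the downward root crossing of the second
  difference coincides with the first-difference optimum; the ascending
  crossing (or, on clean profiles, the curve's first inflection) estimates
  the upper threshold.
- **local Moran** — the per-pixel autocorrelation
  `I_i = ((x_i − μ)/m₂) · mean_{j∈N_i}(x_j − μ)` is high for both the
  homogeneous background and saturated vessels, so a single cutoff
  (default 0.4) separates the cytoplasm from both.

A seeded synthetic generator produces strial-like tripartite images and
z-stacks with per-pixel ground truth, which stands in for manual
segmentation in the validation battery (perturbation robustness, cosine
similarity of manual-surrogate vs machine trends, z-stack consistency,
histogram-reshaping diagnostics).

## Worked example

```r
library(focalseg)

gen <- generate_image(synthetic_spec(seed = 42))
gen$image
#> <raster_image> 256 x 256 pixels (58880 valid)
#>   mean 0.4758  sd 0.1785  skewness 0.943

res <- segment_image(gen$image, seg_config("percentile"))
res
#> <segmentation_result> method percentile, thresholds [0.3771, 0.5052]
#> n = 38863, mean = 0.4427, sd = 0.06746, skewness = 0.01546

perturbation_test(gen$image, seg_config("percentile"), "additive", 0.196)
#> <perturbation_report> additive 0.196: expected 0.63872, observed 0.63857 (err 0.0246%)
```

Reading the numbers: the raw image is right-skewed (0.94) because of the
bright-vessel tail; the 20th/70th-percentile thresholds (0.377, 0.505 in
intensity units) select 38,863 pixels whose distribution is approximately
normal (skewness 0.02) with a tighter spread — the histogram reshaping
expected when the cytoplasm has been isolated.  Adding 0.196 to every
pixel and re-segmenting reproduces the shifted mean to 0.02%, far inside
the 1.5% robustness bound.

Batch work and the full workflow are also exposed on the command line via
the wrapper installed at `system.file("scripts", "focalseg",
package = "focalseg")`:

```sh
focalseg generate --seed 7 --out run/
focalseg segment --method percentile --out run/seg run/
focalseg validate --perturb additive:0.196 --seed 7 --out run/val
```

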