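# numerispec

Humans and many animals judge the number of items in a display at a glance.
Early visual cortex responds to image contrast at specific orientations and
spatial frequencies — yet its aggregate response tracks numerosity almost
independently of item size and spacing. `numerispec` implements the image
statistic that reconciles these observations, and the modelling pipeline
used to test it against (synthetic or user-supplied) fMRI responses. It is
aimed at visual neuroscientists and psychophysicists studying numerosity
perception and its early visual basis.

## The statistic

For a display normalized to zero on the background and one (or the signed
Weber contrast) in the items, take the 2-D discrete Fourier transform and
collapse |F(u, v)| into annular bins of one cycle/image. The radial power
spectral density falls to a pronounced minimum at the end of the first
harmonic, at spatial frequency *f*₁ ≈ 1.22 · canvas / item-diameter — the
first zero of the circular-aperture spectrum, set by item size rather than
item count. The **aggregate Fourier power**

> *P* = Σ<sub>f ≤ f₁</sub> PSD(f) / (canvas² · √2)

is ≈ 1 for a single unit-contrast circle at any resolution, rises as
roughly *N*<sup>0.47</sup> with numerosity *N*, and is nearly unchanged by
item size, spacing, and (for convex shapes above three corners) shape. The
first-harmonic limit is detected automatically: the lowest frequency above
the spectral peak where the first or second discrete derivative of the PSD
peaks locally and the PSD has fallen below 25% of its global maximum.

Around the statistic the package provides:

* **Stimulus generation** — constant-area / constant-size /
  constant-perimeter / high-density dot configurations, single-circle,
  spacing, numerosity (1–175), polygon and star generalization series, and
  dot pairs connected by bars or illusory-contour inducers (with
  split-and-rotated controls carrying identical pixel mass).
* **Feature battery** — per-item and total area and perimeter, convex-hull
  area/perimeter, luminance/edge/number densities, RMS contrasts,
  Laplacian-of-Gaussian filter responses and the high/low
  spatial-frequency response ratio, and spatial pRF predictors.
* **Response models** — monotonic (GLM on a log- or linearly-scaled
  feature sequence convolved with a canonical double-gamma HRF) and tuned
  (logarithmic Gaussian in numerosity, μ ∈ [1.05, 6.95], grid search by
  correlation) fits to 44-TR averaged stimulus cycles, with split-half
  cross-validation that refits only amplitude and baseline (sign-locked
  for monotonic models).
* **Statistics** — eccentricity binning (0.2°), cumulative-Gaussian
  sigmoid / quadratic eccentricity-profile fits with 1000-sample
  bootstraps, Wilcoxon signed-rank model comparisons with
  Benjamini–Hochberg correction, and scaled-function comparisons against
  digitized neural-network response lines.
* **Synthetic cohorts** — voxel populations with known monotonic/tuned
  ground truth and eccentricity-dependent signal-to-noise, so the whole
  pipeline is testable without any data download.

## Worked example

```r
library(numerispec)
set.seed(1)

# one unit-contrast circle: the normalization anchor
aggregate_power(display_spec(tibble::tibble(
  shape = "circle", x = 384, y = 384, size = 30)))
#> # A tibble: 1 × 5
#>     raw normalized f1_limit global_peak_freq canvas_px
#>   <dbl>      <dbl>    <int>            <int>     <int>
#> 1 821365.      0.985       29               16       768

# mean power vs numerosity in one fMRI stimulus configuration
sapply(1:7, function(n)
  aggregate_power(make_configuration_display("constant_size", n))$normalized)
#> [1] 0.985 1.253 1.547 1.769 1.975 2.153 2.331
```

Power is ≈ 1 for one circle (the raw first-harmonic sum divided by
768² · √2), and grows sub-linearly — `7^0.47 ≈ 2.5` — as numerosity rises,
even though every item has the same size. `power_law_exponent_experiment()`
runs the full 1–175 series and fits the exponent;
`fit_voxels()` + `fit_eccentricity_profile()` carry simulated or measured
voxel time series through model fitting, cross-validation and
eccentricity-profile statistics. Each result is a tibble; fitted profile
objects have `tidy()`, `glance()` and `autoplot()` methods.

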