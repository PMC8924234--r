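---
title: "Aggregate Fourier power, numerosity, and response-model fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregate Fourier power, numerosity, and response-model fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numerispec)
```

## The model

Early visual neurons respond to contrast at particular orientations and
spatial frequencies, so the cortical image representation resembles a 2-D
Fourier decomposition. For displays of discrete items on a uniform
background, the magnitude spectrum has a compact low-frequency lobe — the
first harmonic — whose extent is set by item size: larger items move power
to lower frequencies over a narrower band, while hard edges put power at
amplitudes that fall as 1/frequency. Bandwidth (∝ frequency) times
amplitude (∝ 1/frequency) is constant, which is why the summed magnitude
within the first harmonic barely changes with item size or spacing, yet
accumulates (sub-additively, about as *N*^0.47^) as items are added. At
fixed contrast this makes aggregate first-harmonic power a usable
single-number proxy for numerosity, and the package's central quantity:

$$P \;=\; \frac{1}{\text{canvas}^2\sqrt{2}} \sum_{f \le f_1} \mathrm{PSD}(f),
\qquad \mathrm{PSD}(f) = \sum_{f-0.5 < \sqrt{u^2+v^2} \le f+0.5} |F(u,v)|$$

with the zero-frequency term excluded and bins of one cycle/image up to the
Nyquist frequency. The divisor makes one unit-contrast circle come out at
≈ 1 at any resolution.

## Detecting the first-harmonic limit

`first_harmonic_limit()` returns the lowest frequency above the global PSD
maximum at which (a) the first or second discrete forward difference of the
PSD attains a local maximum — the sharpest change in the spectrum, i.e. the
bottom of the dip that closes the first harmonic — and (b) the PSD has
fallen below 25% of its global maximum. If no frequency qualifies, the
global minimum above the peak is used; a spectrum that rises monotonically
above its peak is an error with a diagnostic dump. Ties break toward the
lower frequency. These choices ("local maximum scanning upward",
forward differences) are one concrete reading of an ambiguous verbal rule;
the threshold and the detection basis are arguments, not constants.

Two well-motivated bases exist, and neither dominates:

* **`basis = "sum"` (default)** — the rule runs on the annulus-summed
  magnitude spectrum exactly as defined above. This reproduces the
  power-law exponent (0.47) for multi-item displays and the one-circle
  anchor, but for very large single items (diameter ≳ 200 px on a 768-px
  canvas) the annulus population factor (∝ f) props the low-frequency lobe
  up so the dip never crosses the 25% threshold, and the limit lands too
  high (power ≈ 1.4 instead of ≈ 1 at 240 px).
* **`basis = "counts_corrected"`** — the threshold is evaluated on the
  per-annulus *mean* PSD, which restores the dip for large single items but
  badly mis-limits dense multi-item displays (their per-annulus mean
  spectrum is dominated by a handful of huge low-frequency coefficients).

We default to the stated summed definition and expose the variant; users
analysing single items larger than ~1/4 of the canvas should prefer the
counts-corrected basis. For shapes whose spectrum differs with orientation
(polygons, stars), `orientation_resolved_power()` partitions the frequency
half-plane into 36 sectors of 5° and detects a limit per sector on the
sector's occupied-bin, per-coefficient profile; sectors with fewer than
three occupied bins fall back to the global limit.

## Stimulus generation

Displays are square mid-grey canvases (default 768 px) with items placed in
a circular region. Visual-degree quantities map to pixels at 350 px per
0.75° (the stimulus region radius), configurable via `px_per_degree`
arguments. A pixel belongs to an item when its centre lies inside the
analytic shape: no anti-aliasing, so rendering is deterministic and every
geometric assertion can be made on pixel masks. Weber contrast *c* maps an
item to luminance `background * (1 + c)`.

The four fMRI configurations conserve, across numerosities 1–7 (plus the
20-item baseline): total item area (`constant_area`; also the high-density
variant, which packs the same items into a sub-region of half the stimulus
radius placed at random), item diameter (`constant_size`, 30 px), or total
perimeter (`constant_perimeter`). The reference diameter at numerosity 1
(60 px for area/perimeter/density) and the 2-px minimum gap are package
choices — the source protocol states neither — and are arguments.

Placement ("random but approximately homogeneous") is uniform rejection
sampling with a minimum edge-to-edge gap. The numerosity-175 series (16-px
items ≥ 24 px apart in a 700-px region) needs a packing at ~0.60 coverage
of the centre space, beyond the ~0.547 jamming density at which random
sequential placement stalls, so dense requests fall back to a
pairwise-repulsion relaxation from a random start, yielding an amorphous
jammed packing. (A jittered-lattice fallback was rejected: its
near-crystalline order suppresses low-frequency spectral power and visibly
bends the power-vs-numerosity curve at high numerosity.)

Dot-pair displays use 30-px dots, 4-px-wide bars spanning the edge-to-edge
gap, and 4-px background-coloured inducers carved 10 px into each dot. The
rotated controls split the element at the midpoint and rotate each half by
90° about its dot centre; centres sit on integer pixels, so the rotation is
an exact bijection of the pixel grid and the controls carry *exactly* the
same pixel mass as the connected versions.

## Contrast manipulations

For contrast analyses the normalized field holds each item's signed Weber
contrast (`contrast_mode = "signed_deviation"`). Power is linear in |c|, so
dividing by the mean item contrast compensates. Two packaged experiments
probe contrast structure using a compact group of seven 16-px circles
(group radius 50 px — the protocol's "group of seven circles" leaves the
region unstated; a dense group is the only geometry in which item-vs-rest
luminance differences matter, and in sparse 700-px regions the mixture
effect vanishes):

* `contrast_mixture_experiment()` — random black/white mixtures vs
  all-black items, paired geometries. Random signs erase the pair-position
  anticorrelation that a minimum-distance packing imposes on the spectrum,
  raising mean power by ~1.5% at this density.
* `contrast_range_experiment()` — per-item |c| uniform on 0.5 ± 0.05
  versus 0.5 ± 0.425. The spread (2.5–97.5 percentile width) of per-display
  contrast-normalized power grows by roughly 300%, the mean by only ~10%
  (the aggregate follows the root-mean-square rather than the mean of item
  contrasts, so wider ranges shift it slightly upward even after
  normalization).

## Response models

The block design is one averaged 44-TR cycle (TR 2.1 s): numerosities 1–7
ascending for two TRs each, eight TRs at 20 items, 7–1 descending, eight
more TRs at 20. Predictors are neural amplitude sequences convolved
circularly with a canonical double-gamma HRF (peak 6 s, undershoot 16 s,
dispersions 1 s, ratio 1/6, truncated at 30 s, unit peak of the continuous
kernel — all arguments); circular convolution is the physically correct
edge handling for a cyclically repeating stimulus.

* **Monotonic**: amplitude = log (default) or linear feature value;
  baseline and β by ordinary least squares. The sign of β separates
  increasing from decreasing responses. `choose_scaling()` picks one global
  scaling per feature by summed variance explained (ties to log).
* **Tuned**: amplitude = exp(−(log x − log μ)² / 2σ²), evaluated at the
  presented numerosity including the 20-item baseline (the far tail is
  what separates narrow from broad tuning). Candidates on a log-spaced
  grid, μ: 60 points in [1.05, 6.95] — within the presented range, beyond
  which tuning parameters are not identifiable — and σ: 40 points in
  [0.05, 2] log-units; the grid resolution is a package choice. The best
  candidate is selected by correlation, then amplitude and baseline are
  refit by least squares.

Cross-validation freezes shape parameters and refits amplitude/baseline on
the held-out half (amplitudes drift between scanning sessions); monotonic
refits may not flip sign — an infeasible sign clamps β to 0 and records a
non-positive cross-validated variance explained. Variance explained pools
across stimulus configurations as summed explained over summed total
variance, so configurations with more signal weigh more. Voxel inclusion
(some model's fit-half R² > 0.2) is applied on the fitting half only, never
the evaluation half, to keep selection and comparison uncoupled.

## Synthetic cohorts and what they do (not) show

`simulate_cohort()` draws voxel eccentricities uniformly on [0, 5.5]°,
builds noiseless monotonic or tuned responses, and adds white Gaussian
noise scaled so the expected variance explained follows a generating
profile — a decreasing cumulative-Gaussian sigmoid for early-visual-like
maps, flat for association-like maps — with two independent split halves.
AR(1) noise is available (`ar1`), default off. The generator emulates the
*statistical* structure the analysis assumes (per-voxel 44-TR cycles,
eccentricity labels, known ground truth); it does not model empirical fMRI
noise spectra, spatial correlation between voxels, drift, or
between-session amplitude changes. Green tests therefore certify the
estimators and the pipeline's wiring, not the physiology.

One structural finding from these simulations: tuned voxels generated with
preferred numerosity below one (decaying responses) are fit almost
perfectly by the *tuned* model pinned at its μ = 1.05 boundary, while the
log-linear monotonic-decreasing model fits them much worse. What survives
is the direction: such voxels always yield negative monotonic β and
boundary-pinned μ, consistent with reading monotonically decreasing sites
as tuning below the tested range.

## Eccentricity profiles and comparisons

Variance explained is binned by pRF eccentricity at 0.2° from 0 to 5.5°
(mean, SEM, empty bins dropped). Profiles are fit to bin means with either
a four-parameter cumulative-Gaussian sigmoid, VE(e) = min + (max −
min)(1 − Φ((e − inflection)/slope)), or a three-parameter quadratic; 1000
bootstrap resamples of the unbinned voxels give per-parameter medians as
point estimates and 2.5/97.5-percentile curve envelopes. The nonlinear fits
use bounded Levenberg–Marquardt with five data-driven starts and a
Nelder–Mead fallback for degenerate (e.g. flat) resamples; resamples that
still fail are redrawn, capped at 10% of draws. Family selection takes the
better correlation between fitted curve and bin means, with near-ties going
to the quadratic (fewer structural assumptions). The bootstrap pools voxels
across participants (a `fit_eccentricity_profile()` choice; within- vs
across-participant resampling is exposed only through the input table).

Model comparisons use paired two-sided Wilcoxon signed-rank tests on
per-hemisphere median cross-validated VE with Benjamini–Hochberg FDR
correction over the declared family; the signed normal-approximation Z
accompanies the exact small-sample p. Linear mixed-effects stages
(map × eccentricity-range) are deliberately left to standard tools (`lme4`,
`emmeans`) on the tidy fit tables this package produces; they are not
reimplemented here. `compare_nn_lines()` normalizes digitized network
response lines to a common 0–1 range (preserving between-line offsets),
scales candidate functions — e.g. the package's own power-vs-numerosity
curve, or log(N) — by least squares, and compares per-line correlation sets
with paired t-tests alongside a quadratic reference fit.

## Numerical choices and problem sizes

Sub-second determinism choices worth knowing: pixel-centre membership (no
anti-aliasing); trigonometric values snapped at multiples of π/2 so
axis-aligned rectangles rasterize with clean half-open boundaries; the
relaxation placer treats ≤ 10⁻⁹ px constraint violations as satisfied;
tuned-candidate time courses are cached per (sequence, grid, kernel). The
test-suite and example problem sizes — e.g. 16 log-spaced numerosities × 3
displays for the exponent, 80 displays per contrast condition, cohorts of
a few hundred voxels, 60–120 bootstrap resamples — are the package's
scaled-down defaults for interactive work; `power_law_exponent_experiment()`
and `fit_eccentricity_profile()` take the full sizes (10+ displays per
numerosity, 1000 resamples) as arguments.

This package has no command-line interface by design: it is an analysis
library, and `run_pipeline()` plus the exported readers/writers are its
composition surface.

## Known limitations

* The first-harmonic rule is heuristic; both bases mis-limit some extreme
  display (very large single items for `"sum"`, dense multi-item fields
  for `"counts_corrected"`). Triangles lack a clear spectral minimum and
  their limit (hence power) is less stable than other polygons'.
* Rendering is binary; anti-aliased stimuli (as produced by presentation
  software) will have slightly different spectra, mainly for items a few
  pixels across.
* The LoG feature "summed response" is rectified (|·|) because a zero-mean
  filter sums to zero; squared-energy summation is available via
  `rectify = "square"`. Filters are applied to the background-zeroed field.
* Synthetic cohorts use white (optionally AR(1)) noise; none of the
  structured noise of real fMRI.
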