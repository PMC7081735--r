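---
title: "Automated retinal boundary detection and thickness quantification in rodent OCT"
author: "octseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated retinal boundary detection and thickness quantification in rodent OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octseg)
```

## The problem

Spectral-domain OCT gives longitudinal, in-vivo cross sections of the rodent
retina, which makes it attractive for preclinical studies of retinal disease
(for example oxygen-induced retinopathy models) where the readout is total
retinal thickness over time. Manual tracing of boundaries does not scale and
is subjective; `octseg` implements a fully automated pipeline that segments
two boundaries in every A-scan of every B-scan — the innermost retinal layer
boundary (IRL, the vitreoretinal interface) and the outermost retinal layer
boundary (ORL, just above the sclera) — and aggregates the per-A-scan
thickness `ORL − IRL` into a per-volume estimate with an uncertainty.

## The algorithm

All positions are depths in micrometres measured from the top (vitreous
side) of the frame; pixel `k` (1-based) lies at depth `(k − 1) ·
axial_spacing`. Every parameter is expressed in physical units and converted
to pixels per volume, so one parameter set applies across scanners and
export resolutions.

1. **Sclera anchor.** The B-scan is blurred with a Gaussian of σ = 20 µm.
   In rodent scans the sclera is the brightest object, so the absolute
   intensity maximum of each smoothed A-scan localizes the scleral band
   centre (ties resolve to the smallest depth).
2. **Axial intensity slope.** Each column is smoothed along depth with a
   Gaussian of σ = 2 µm and differentiated by central differences
   (one-sided at the borders), giving intensity change per micrometre;
   positive slope means intensity increasing with depth.
3. **ORL.** Scanning from the sclera centre toward the vitreous, the first
   strict local minimum of the slope is the ORL: the steepest
   retina-to-choroid intensity descent.
4. **IRL.** Among strict slope maxima lying *strictly more than* 120 µm
   above the ORL, the highest-valued peak is the IRL; the exclusion zone
   prevents intra-retinal edges (for instance plexiform banding) from being
   mistaken for the vitreoretinal interface. Equal-amplitude candidates
   resolve toward the ORL, the conservative (thinner) choice.

A "valley"/"peak" is a strict local extremum over a three-sample
neighbourhood after smoothing; plateaus of equal values collapse to their
depth-wise midpoint, which keeps the rule deterministic on discrete data.
Per-A-scan failures are recorded (`no_valley`, `no_peak`, `out_of_frame`,
the last flagging a scleral maximum on the deepest row) and never abort a
B-scan.

### What the slope is computed on

The boundary rules operate on the axial derivative of a smoothed profile,
and there is a genuine design choice in *which* profile is differentiated.
Differentiating the raw B-scan (after only the σ = 2 µm pre-smoothing)
localizes boundaries at native axial resolution, but the "first valley
above the sclera" rule is then extraordinarily fragile: even 1–2 %
multiplicative speckle creates spurious strict minima between the sclera
and the true ORL, and the detected boundary collapses onto the first noise
dip. Differentiating the coarse-smoothed image instead sacrifices nothing
in the noiseless limit — Gaussian smoothing is symmetric, so the slope
extremum of an isolated boundary stays at the transition midpoint — and
keeps the valley/peak rules stable under realistic speckle (the σ = 20 µm
blur suppresses the noise derivative by more than an order of magnitude
relative to boundary slopes). `octseg` therefore defaults to
`slope_source = "smoothed"`, and exposes `"raw"` for low-noise data or for
probing localization at native resolution. For isolated boundaries with
transition scales up to ~10 µm the two choices agree to within one axial
pixel; they differ materially only when distinct edges approach within a
few smoothing scales of each other.

Whether the coarse blur acts on both axes or only along depth is likewise
exposed (`coarse_axes`, default `"both"`): a lateral component is a cheap
regularizer against column-to-column jitter of the sclera anchor and has no
effect on axial localization of the boundaries.

## Parameters

| parameter | unit | default | role |
|---|---|---|---|
| `sigma_coarse` | µm | 20 | blur for sclera anchoring; large enough to make the band the global column maximum under speckle |
| `sigma_slope` | µm | 2 | pre-differentiation smoothing of the profile the slope is taken from |
| `min_irl_offset` | µm | 120 | ORL→IRL exclusion zone (strictly-greater rule) |
| `pct_error_threshold` | % | 25 | B-scans with a larger thickness coefficient of variation are discarded (strictly-greater rule) |
| `min_valid_fraction` | — | 0.5 | minimum fraction of segmentable A-scans for a B-scan to be summarized; also requires ≥ 2 valid A-scans so a sample SD exists |
| `weighting` | — | `"sd"` | volume-mean weight `1/SD` per B-scan; `"sem"` uses `sqrt(n)/SD` |
| `zero_sd_weight_factor` | — | 10 | a zero-SD B-scan takes the largest finite weight × this factor, so "most precise dominates" without an infinite weight |

`min_valid_fraction` and the zero-SD rule are artifacts of making the
aggregation total: a weight of `1/SD` is undefined at `SD = 0`, and a
B-scan segmented in only a handful of columns should not enter the volume
mean on equal terms. Both are configurable.

## Aggregation

Within a B-scan the mean and sample (n−1) standard deviation of valid
A-scan thicknesses give the *percentage error* `100·SD/mean` (the
within-scan coefficient of variation — the only within-B-scan error measure
available at this stage). B-scans whose percentage error exceeds 25 % are
discarded; a value exactly at the threshold is retained. The volume mean is
the inverse-SD weighted average of the retained B-scan means, and the
reported uncertainty is the standard error *among B-scans*: the unweighted
sample SD of retained means divided by √m, undefined (reported as null)
when fewer than two scans survive. Group comparisons across animals use
one-way ANOVA (α = 0.05) with Bonferroni-corrected pairwise pooled-variance
t-tests (raw p × number of pairs, capped at 1).

## The phantom generator

`phantom_spec()` describes a parametric synthetic volume whose defaults
emulate a Spectralis-style rodent acquisition: 7 B-scans 240 µm apart, 768
A-scans per B-scan, 496 depth pixels at 3.87 µm/px (≈ 1.9 mm window; the
axial pitch is a plausible, configurable choice — real calibration must
always come from the scan metadata). An A-scan is a piecewise-constant
profile — vitreous 0.04, retina 0.60, choroid 0.25 in arbitrary linear
units — with logistic transitions of scale 5 µm at the two retinal
boundaries and a Gaussian scleral band (peak 1.0, SD 25 µm) as the
brightest structure. The default boundary depths put the retina at
800–1000 µm and the band centre 130 µm below the ORL: rat choroid is on
the order of 50–100 µm thick, so a ~130 µm gap between the outer retinal
boundary and the centre of a ~100 µm sclera is anatomically reasonable.
Ground truth is defined as the logistic transition midpoint / band centre,
which coincides with the slope extremum the detector targets, so
"sub-pixel accuracy" is well defined. All three surfaces share a quadratic
lateral sag (15 µm) and an optional per-B-scan tilt, preserving a uniform
true thickness; thickness families are built by varying `irl_depth` across
specs.

Speckle is modelled as unit-mean multiplicative gamma noise (shape `k`,
contrast `1/√k`), applied per pixel before any smoothing, plus optional
additive Gaussian read noise; the default `k = 50` (≈ 14 % contrast) is a
plausible residual after ~100-frame real-time averaging. `generate_volume()`
is bit-reproducible given the spec seed, and reseeding changes only the
noise realization, never the ground truth. `inject_distractor()` adds a
narrow bright band (default 15 µm wide) with its leading edge at a chosen
offset above the ORL, producing a controlled competing slope peak for
exclusion-zone experiments; it is kept narrow so that coarse smoothing
attenuates it and the sclera anchor survives even strong probe amplitudes.

**What the phantom does not emulate:** depth-dependent signal attenuation
and shadowing, spatially correlated speckle grains, motion and vessel
shadows, curvature of the eye beyond low-order polynomial surfaces, and
intra-retinal sublayer banding (except as explicit distractors). Passing
the phantom suites therefore demonstrates correctness of the *rules* and
robustness to first-order speckle, not performance on pathological scans.

## Numerical choices

* Gaussian kernels are sampled at integer pixel offsets, truncated at 4σ
  (minimum radius one pixel) and renormalized; boundaries are handled by
  mirror reflection without repeating the edge sample, so constants are
  preserved exactly and linear ramps are preserved away from borders.
* Smoothing accumulates the same weighted sum in the same order for every
  output sample, so a constant input yields a bit-identical constant —
  the strict extremum detector downstream depends on that.
* Derivatives are central differences on the smoothed profile, one-sided
  at the borders.
* Detection depends only on intensity *ordering*, so segmentation is
  exactly invariant to positive affine intensity maps `a·I + b`, `a > 0` —
  the property that makes results independent of export scaling.
* Tie-breaks: equal sclera maxima → smallest depth; equal IRL peak
  amplitudes → closest to the ORL. Both are deterministic and conservative.

## Verification problem sizes

The shipped tests recover, behaviourally, every constant of the algorithm:
smoothing scales from impulse-response second moments (at 4 µm and 0.5 µm
sampling), the 120 µm exclusion zone from a distractor-offset sweep at 1 µm
axial sampling (recovered 121 µm; the residual reflects sweep-step and
pixel quantization), and the 25 % discard rule from a percentage-error
sweep. Ground-truth recovery runs noiseless volumes across a 150–300 µm
thickness grid in 25 µm steps (error bound: one axial pixel) and 100
speckled volumes at `k = 50` at the full default geometry (mean bias bound:
5 µm). Boundary detections are cross-checked against brute-force extremum
enumeration on 100 random smoothed columns, and the ANOVA stage against a
raw sums-of-squares oracle on 100 random datasets.

## Known limitations

* The ORL "first valley" rule has no prominence criterion; with
  `slope_source = "raw"` it is unusable under speckle (see above), and even
  in the default mode very low-contrast choroids with wide scleral gaps can
  admit spurious valleys.
* An admissible distractor edge stronger than the true vitreoretinal slope
  peak *will* be selected — an inherent failure mode of the published
  highest-peak rule that the exclusion zone only mitigates, demonstrated in
  the distractor tests.
* Only two boundaries are segmented; intra-retinal sublayers and choroidal
  boundaries are out of scope, as are eye-tracking/registration across
  timepoints and proprietary scanner formats (export image stacks with a
  JSON spacing sidecar instead).

## A worked example

```{r example, eval = FALSE}
spec <- phantom_spec(seed = 42)          # default 7 x 768 x 496 geometry
gen <- generate_volume(spec)             # volume + exact ground truth
ana <- analyze_volume(gen$volume)        # segment, summarize, filter, weight
ana$volume
#> Volume thickness: 199.63 um (SE 0.05 um, 7 B-scans retained)
mean(gen$truth$thickness_um)
#> [1] 200
```
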