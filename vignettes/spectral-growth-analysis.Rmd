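---
title: "Spectral analysis of growth patterns on fish scales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral analysis of growth patterns on fish scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scalegram)
```

## The measurement problem

Atlantic salmon scales record growth as a sequence of mineralized ridges
(circuli). Wide inter-circuli spacing marks fast (summer) growth, narrow
spacing marks slow (winter) growth, and one summer–winter cycle corresponds
to one year. The classical workflow has an analyst click circulus positions
along a single radial line, which is slow, operator-dependent, and throws
away everything the rest of the image records. Three features of real scales
frustrate naive automation: local ridge imperfections, anisotropy (the scale
is not circular, so the focus-to-edge distance varies with angle even though
growth time does not), and a posterior field with weak ridge patterning.

`scalegram` implements a semi-automated spectral alternative. The only
manual input is the focus annotation (one pixel pair per image); everything
downstream is deterministic.

## The pipeline

1. **Unwrap.** Saturation values are sampled along radial lines every
   `delta_theta` degrees (default 0.1°, i.e. 3600 transects) at 1-px radial
   steps, with bilinear interpolation of the four neighboring pixels.
   Nearest-neighbor sampling would alias the fine outermost circuli that the
   dense angular sampling is meant to capture, which is why interpolation is
   bilinear.
2. **Edge truncation.** The background model (median and MAD of the image
   border frame) drives a sliding-window rule: a transect ends at the last
   sample before the first `edge_window`-px window whose variance is at most
   `edge_var_mult` times the background variance and whose mean is within
   `edge_level_mult` background standard deviations of the background level.
   This also removes artifacts that lie beyond the rim, such as the scale
   bar. Both comparisons carry a 1e-6 absolute slack so that noise-free
   backgrounds survive interpolation round-off.
3. **Spectrogram.** Each transect is analyzed with a short-window Fourier
   transform: a 200-px window stepped 5 px at a time, each window mean-removed,
   multiplied by a symmetric Hamming taper, and transformed; the one-sided
   amplitude spectrum (bins `k = 1..N/2`, frequency `k/N` cycles/pixel) forms
   one spectrogram column. The window mean is removed because raw saturations
   have a large offset that would otherwise dominate and leak under the taper;
   the DC bin is dropped for the same reason. Columns are indexed by the
   window *center* offset, the documented convention for a quantity that in
   truth describes the whole window.
4. **Stretch.** Column positions are rescaled by the transect length
   (`x' = x/xmax`) and each frequency row is linearly interpolated onto
   `stretch_L` (default 1500) evenly spaced positions of `[0, 1]`. Because
   window centers cannot reach the transect ends, positions outside the
   center span repeat the nearest column rather than extrapolate. Stretching
   the *spectrogram* rather than the transect is the crux: circuli spacing as
   a function of relative radial position is the same at every angle (longer
   radii carry more circuli, not wider ones), so resampling the position axis
   aligns growth phases without touching the frequency content. Stretching
   the raw saturation series instead would rescale every period and bias the
   spacing estimate — this is the anisotropy correction.
5. **Ensemble.** Stretched spectrograms are averaged cell-wise over all
   retained transects (those at least one window long). The package streams
   this average, never materializing all 3600 stretched matrices at once.
   Alongside the mean it accumulates, per stretched column, the variance
   across transects of each transect's own peak bin.
6. **Trace and segmentation.** The growth trace is the frequency of the
   maximum-amplitude bin per stretched column (ties go to the lower
   frequency, favoring the fundamental over harmonics), converted to spacing
   by `spacing_mm = 1/(f * pixels_per_mm)`. The first marine year is the
   span between the first and last runs of at least `run_length` (30)
   consecutive columns with peak variance below `var_threshold` (10).
   Freshwater and return circuli are poorly resolved, so transects disagree
   on the peak there and the variance is high; over the marine year nearly
   all transects report the same bin.

## Units of the segmentation variance

The variance threshold of 10 is only a plausible magnitude if the peak
variance is expressed in squared *bin indices*: in squared cycles/pixel the
statistic could never exceed 0.25². The package therefore computes the
across-transect variance on bin indices and documents the threshold in those
units; it is configurable.

## Spectral resolution

With a 200-px window the frequency bin spacing is 1/N = 0.005 cycles/pixel.
The recovered spacing is the reciprocal of a quantized frequency, so the
spacing quantization error grows with the spacing itself: about `p²/N` for a
local period of `p` pixels (0.5 px at p = 10, 4.5 px at p = 30). This bound
is what the parameter-recovery validation checks against. A window also
averages whatever lies inside it, so within half a window of a phase
boundary the column's spectrum mixes both phases; recovery checks apply a
half-window interior margin for that reason.

## What the synthetic generator emulates

Reference salmon-scale archives are typically available only on request,
not deposited, so validation rests on a generator
whose defaults reproduce the acquisition conditions: 2560 x 1920 frames at
302 px/mm, a whole scale in frame with rim radius 680 px on the minor axis
(transect lengths of roughly 600–900 px), axis ratio 1.25, a bright uniform
background (level 235, noise sd 3) with a dark scale-bar artifact, three
localized ridge imperfections, and a posterior arc spanning 100 degrees.
Each circulus is a dark band with a Gaussian radial cross-section whose
width tracks the local spacing, giving the quasi-sinusoidal waveform the
Fourier analysis assumes; the radial intensity profile of a real circulus is
not documented anywhere we know of, so the Gaussian bump is this package's
choice.

Anisotropy is modeled the way the method itself assumes scales grow: the
spacing law as a function of relative radial position `u = r/R(θ)` is
identical at every angle, and longer axes accumulate more rings before
reaching their rim. Rendering rings as stretched ellipses instead would
scale the local spacing by the axis ratio and make the spectral content
genuinely different across angles — under that (wrong) model no stretching
could reconcile the traces.

Two emulated nuisances deserve comment:

- **Posterior arc.** A literally featureless noisy arc produces uniformly
  random spectral peaks on ~28% of transects, which pushes the peak variance
  above the threshold at *every* column and makes the segmentation rule
  unsatisfiable by construction. Real posterior fields carry weak but
  coherent ridge energy, so the generator attenuates ridge depth there
  (default factor 0.2) rather than deleting it; the factor is configurable
  down to 0.
- **Flank jitter.** The freshwater and return bands of real images yield
  peak frequencies with broad distributions across transects. The generator
  reproduces this with a per-angle multiplicative spacing factor (log-normal,
  clamped to [0.5, 2]) applied only to flank rings: each transect keeps a
  coherent flank tone, but at an angle-specific frequency. Marine rings are
  generated from the shared unperturbed law, anchored so that an unjittered
  profile has no seam at either phase boundary. Jittering ring *positions*
  instead makes the flank incoherent within each transect; the marine tone
  then wins windows centered well inside the flank and the detected bounds
  overrun the truth by ~2.5% of the stretched axis.

The default growth profile (`salmon_growth_profile()`) is a one-sea-winter
shape: ~5 px freshwater spacing, a rise to ~22 px in the ocean summer, a
~11 px winter band, a partial spring recovery, and a ~8 px return phase,
joined by cosine ramps. Its seasonal transitions are deliberately abrupt
(shorter than one analysis window), which is realistic but makes the window
spectra bimodal at the handoffs — there the argmax column is an unstable
competition between two peaks, an SWFT property independent of anisotropy.
Validation experiments that need to isolate *stretch alignment* therefore
use a smoothly modulated marine profile (a single seasonal cosine cycle,
12 to 22 to 12 px) whose within-window frequency drift stays below one bin.

What the generator does not emulate: photorealistic texture, regenerated
scales, body-position effects, dirt, illumination gradients, or multi-year
marine growth. Passing tests demonstrate that the algorithmic chain recovers
known structure under the stated image model; they cannot certify behavior
on pathologies the model lacks.

## Validation problem sizes

The validation suite balances fidelity against runtime on a single CPU: the
anisotropy experiment uses the default scale geometry sampled at 5°
(72 transects), parameter recovery uses an isotropic 850-px-radius scale at
1° (360 transects), segmentation recovery uses the default geometry at 0.5°
(720 transects), and the end-to-end check runs the full printed
configuration — a 2560 x 1920 image unwrapped at 0.1° into 3600 transects —
twice, asserting bit-identical results.

## Degenerate inputs and tie-breaks

- Transects shorter than one window yield an empty, flagged spectrogram and
  are excluded from the ensemble (their count is reported in QC).
- All-zero spectrogram columns have no defined peak; they are `NA` in the
  trace and excluded from the variance statistic.
- Equal-amplitude ties resolve to the lower frequency.
- A segmentation with no qualifying low-variance run reports `NA` bounds;
  `run_cohort()` excludes such scales from the profile matrix and lists them
  in the QC table.
- Manual-measurement simulation re-draws individual points (up to 100
  attempts) to keep cumulative distances strictly increasing, then fails
  loudly.

## Cohort comparison layer

Classical measurements enter as strictly increasing cumulative circulus
distances along one transect. The spacing between circuli `i-1` and `i` is
assigned to the rescaled position of circulus `i` (the convention is not
standardized; this one is documented and applied consistently), then
linearly interpolated onto the same 1500-point axis as the spectral traces.
Cohort summaries are column-wise mean, sd and CV per group; `pca_profiles()`
is a mean-centered, unscaled PCA (`stats::prcomp`), with 95%
bivariate-normal ellipses (chi-square(2) contour) for display. For the
spectral side, each fish's trace is restricted to its segmented marine year
and that window rescaled to `[0, 1]` before stacking, so fish of different
sizes and return dates are comparable; scales that fail segmentation are
excluded and listed. The manual-side truncation point to the ocean window is
a configuration value (`truncation_fraction`) because no standard value
exists.

## Worked example

```{r example, eval = FALSE}
library(scalegram)

spec <- scale_spec(seed = 9)
img <- generate_scale_image(spec, salmon_growth_profile(), sample_id = "demo")
res <- run_scale(img, spec$center, pipeline_config())
glance(res$trace)
autoplot(res$trace)
```

## Known limitations

- No harmonic suppression: square-wave-like ridge profiles would promote
  harmonics; the generator's smooth cross-section keeps the fundamental
  dominant, but real images with very crisp ridges may differ.
- Segmentation bounds inherit a bias of a fraction of the analysis window
  where flank tones compete with the marine tone; with the default window it
  is well under 1% of the stretched axis on step-edged synthetics, but soft
  gradual transitions blur the generator's own ground truth.
- One-sea-winter scales only; multi-year alignment and stacking are out of
  scope.
- The focus must be supplied; automated focus detection is not implemented.
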