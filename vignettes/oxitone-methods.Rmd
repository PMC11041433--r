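---
title: "Methods: skin-tone-calibrated smartphone pulse oximetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: skin-tone-calibrated smartphone pulse oximetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxitone)
```

## The measurement problem

Transmissive pulse oximetry estimates peripheral blood oxygen saturation
(SpO2) from the differential absorption of two light wavelengths by
oxygenated (HbO2) and deoxygenated (Hb) hemoglobin. A smartphone can act
as a complete oximeter: the screen flashes red and blue in alternation,
the light is guided through tissue (earlobe, fingertip), and the camera
records per-frame mean RGB values. Red and blue are a workable pair
because their absorption responds in opposite directions as blood
deoxygenates — red transmission falls, blue transmission rises.

Melanin, however, attenuates shorter wavelengths more strongly than
longer ones. The resulting wavelength-dependent loss does not cancel in
the standard normalization, so darker skin shifts the measured quantity
itself — a clinically documented bias of commodity oximeters. This
package implements the full processing stack for such a device together
with an image-based skin-tone calibration that removes the bias, and a
physics-based simulator that provides ground truth for every stage.

## The estimation chain

Per window of `window_s` seconds (default 10), each wavelength channel
contributes an AC component (the root-mean-square of the filtered,
zero-centered signal — the pulsatile arterial part) and a DC component
(the mean of the raw signal — baseline transmission). These combine into
the ratio of ratios

$$R = \frac{AC_{red}/DC_{red}}{AC_{blue}/DC_{blue}},$$

which is mapped to SpO2 percent either by the affine calibration
`SpO2 = 79.3 R - 5.7` (the packaged linear model) or by a fitted
quadratic model. Heart rate is 60 times the dominant periodogram
frequency of the filtered signal inside the pass band.

Signal conditioning follows common PPG practice: a 4th-order Butterworth
band-pass at 0.5–2 Hz (30–120 bpm) applied forward-backward for zero
phase, followed by Savitzky–Golay smoothing (3rd order, 35 samples). AC
is computed from the filtered signal, DC from the raw signal; windows
are non-overlapping and a trailing partial window is dropped.

Choices the literature leaves open, fixed here:

* **Filter family.** Only the cutoffs are canonical; we use Butterworth
  (maximally flat) order 4, applied twice (forward/backward), so the
  effective attenuation at the cutoffs is −6 dB.
* **R orientation.** Red over blue, inferred from the positive slope of
  the packaged linear map and standard practice (in red/IR oximetry R
  rises as saturation falls; with a blue reference the fitted slope is
  positive on bench data).
* **Windows** are non-overlapping; RMS is taken about each window's own
  mean.
* **Heart rate** uses a zero-padded, Hann-windowed periodogram peak with
  parabolic interpolation rather than beat counting — robust on the
  short 20–30 s captures this device produces.

### Numerical edge handling

Zero-phase IIR filtering needs the signal extended beyond its ends; we
use odd-symmetric extension long enough for the slowest filter pole to
decay below 1e-9. The Savitzky–Golay stage reproduces polynomials up to
its order exactly everywhere by evaluating the boundary-window
polynomial at the edges — but that boundary polynomial does not
attenuate an oscillation the way the interior kernel does, which
inflates the AC of the first and last window. The pipeline therefore
excludes a settling margin (`edge_trim_s`, default 2 s) from AC and
heart-rate computation in windows touching a signal edge; DC, window
boundaries and window counts are unaffected. Without this margin the
first window of a noiseless run carries an SpO2 error of roughly 0.7
points; with it, below 0.1.

Degenerate inputs are flagged, not crashed on: windows with
non-positive DC or zero blue AC yield `NA` R values and are counted as
undefined; an all-zero frame is labeled `unknown`; a flat signal yields
`NA` heart rate with a warning.

## Demultiplexing and purple frames

The capture app alternates screen color every frame, so a 30 Hz camera
yields two 15 Hz channel streams. A frame that straddles a color
transition contains both illuminants (a "purple" frame) and is
unusable. Labeling uses channel dominance: a frame is mixed when both
its red and blue means exceed a threshold, by default 40% of the log's
per-channel maxima (the artifact is named in the field; no published
threshold exists, and the fraction is configurable). Channels are
resampled onto a uniform grid at half the nominal frame rate by linear
interpolation; the two grids are offset by half a frame period, which
is below half an output sample and treated as aligned. Timestamp jitter
beyond 50% of a frame period warns rather than errors.

## Skin-tone classification and calibration

A printed six-patch Fitzpatrick reference strip placed in the camera
frame anchors classification against ambient lighting: the measured
mean RGB of the skin patch is compared against the measured strip
patches (not the packaged constants), and the class with the smallest
Euclidean RGB distance wins, ties to the lower class. A
luminance-grayscale variant (ITU-R BT.601 weights 0.299/0.587/0.114 —
the standard choice where the source says only "luminance-weighted") is
available and agrees with the RGB method on the packaged fixture tones.

Tone normalization is multiplicative: for each class, the coefficient
is the reference tone's transmission ratio divided by that class's
ratio, so the reference class (3) always has coefficient 1. The
packaged table carries the bench-derived constants for classes 2
(1.0326 red/IR, 1.0340 red/blue), 3 (1, 1) and 5 (0.8794 red/IR,
1.2396 red/blue). The coefficient is applied to R before the SpO2
mapping (the application point is not fixed by the source; pre-map
multiplication of R is the package's documented convention, and the
inverse operation restores the raw value exactly).

Because no R raster package ships in this environment, images are plain
arrays (`height x width x 3`) with plain-text PPM (P3) read/write;
regions are explicit 0-based half-open pixel rectangles, and no
automatic strip localization is attempted.

## The forward simulator

All ground truth comes from a modified Beer–Lambert model:

$$I(b, t) = I_0(b)\,10^{-[\varepsilon_{Hb}(b)(1-s) +
\varepsilon_{HbO2}(b)\,s]\,c\,d(t) - A_{tone}(k, b)},$$

with pulsatile path length
$d(t) = d_0(1 + a\,w(t))$, where $w$ is a normalized pulse waveform
(raised-cosine systolic lobe plus a 25%-amplitude dicrotic lobe, peak
exactly 1, trough exactly 0). Extinction coefficients are
order-of-magnitude values satisfying the qualitative spectral
constraints ($\varepsilon_{Hb} > \varepsilon_{HbO2}$ at 620 nm, the
reverse at 465 nm); tests rely on the constraints, not the specific
numbers, and all constants are overridable.

Two mechanisms make the simulated world bias-faithful:

* **Tone attenuation** $A_{tone}$ is an additive optical density,
  linear in Fitzpatrick class and stronger for blue (0.13 per class)
  than red (0.07) or IR (0.04).
* **Shunt light** (1% of source intensity) reaches the camera without
  traversing the pulsatile analyte. A purely multiplicative attenuation
  would cancel in AC/DC; the shunt dilutes the pulsatile fraction of a
  heavily attenuated channel more than a bright one, so darker tones
  shift the two channels' AC/DC quotients *unequally* — R itself is
  biased, not just signal amplitude. The attenuation magnitudes were
  set (before any test was written) so the class-5 vs class-2 R
  difference at fixed SpO2 falls in the 4–18% range observed on bench
  hardware, and then frozen.

Frames carry 2% crosstalk of the dominant illuminant into the other
channels, optional mixed frames with configured probability, and
additive Gaussian noise on each frame mean. Frame means average
millions of pixels, so realistic per-frame noise is far below one
8-bit count; the default `noise_sd = 0.05` was calibrated so the
simulated bench's 10-fold cross-validated error statistics match the
physical instrument's reported performance (simulated RMSE 0.71 / MAE
0.47 / R² 0.985 against reported 0.7 / 0.5 / 0.97), then frozen. The
default ex vivo run is a linear 95%→75% desaturation over 4005 s at a
60 bpm pump rate — 4005 rather than 4020 s because demultiplexing trims
a fraction of a second, and 4005 s is what yields exactly 400
ten-second windows.

What the generator does *not* emulate: motion artifacts, ambient-light
leakage, LED spectral width (bands are monochromatic), scattering
(Beer–Lambert only), camera quantization, and sensor nonlinearity. A
green end-to-end test therefore establishes the correctness of the
processing chain and the internal consistency of the physics, not
field performance on human subjects.

## Models and evaluation

`fit_linear` is ordinary least squares. `fit_quadratic` is degree-2
polynomial least squares on the standardized R value: the environment
ships no SVM implementation, and on a one-dimensional predictor a
degree-2 polynomial spans the same hypothesis class as a
quadratic-kernel machine, so this is the documented deterministic
fallback for the quadratic-kernel regressor. Predictions are clamped to
[0, 100]. Cross-validation shuffles fold assignments under an explicit
seed and pools out-of-fold predictions before computing R², RMSE, MSE
and MAE (so `rmse^2 == mse` holds by construction).

Note that the packaged linear map (m = 79.3, b = −5.7) is a *bench
calibration of the physical device*; the simulator's R scale differs,
so simulated runs should be mapped with a model fitted on simulated
windows (as the worked example in the README does), not with the
packaged constants.

## Bias statistics

`one_way_anova` is the classical between/within sum-of-squares
decomposition; `anova_from_summary` reconstructs F from per-group
(n, mean, sd) when only published moments are available, and is
algebraically identical to the raw-data route in exact arithmetic.
P-values are reported to machine precision. Pairwise tone comparisons
use `100·|a−b|/max(a,b)`: published difference tables of this kind
cannot be reproduced from their own rounded ratio cells under any
standard formula, so the package fixes one bounded, symmetric formula
and documents the discrepancy rather than chasing printed percentages.
Post-hoc corrected pairwise tests (Tukey, etc.) are out of scope.

Units caveat: published tone-ratio dispersions of the form "SD 0.11%"
are interpreted as 0.0011 in ratio units; with group means near 0.8 the
reconstructed F is then within an order of magnitude of the published
value, which is as close as rounded moments permit.

## Known limitations

* The calibration coefficients packaged here are transcriptions of
  bench constants; deriving fresh coefficients requires a reference
  measurement session per tone (supported via `derive_coefficient`).
* The quadratic fallback is exactly quadratic; a true epsilon-insensitive
  SVR would differ in its treatment of outlier windows.
* Channel alignment tolerates only the half-sample offset produced by
  alternating frames; captures with dropped frames rely on the linear
  interpolation of the demultiplexer.
* SpO2 below the calibrated 75–100% range is extrapolation and is
  clamped, not validated.
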