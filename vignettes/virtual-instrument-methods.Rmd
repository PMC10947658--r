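---
title: "A virtual fluorescence imaging box: models, calibration procedures, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A virtual fluorescence imaging box: models, calibration procedures, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorbox)
```

Open-hardware fluorescence imaging boxes pair addressable excitation LEDs,
interchangeable emission filters and a consumer RGB camera into an enclosed
imaging instrument for well plates, gels, resolution charts, minerals and
living specimens. `fluorbox` implements such an instrument *in silico* — a
forward model that renders what the camera would record — together with the
full set of characterization and quantification procedures one runs against
the real device: dark-frame black-level statistics, color-chart accuracy,
lens-distortion and resolution-target analysis, plate flatness and
flat-field correction, exposure-sweep dose–response analysis with limit of
detection and dynamic range, gel lane densitometry, long-pass filter-series
spectral reconstruction, an anthocyanin excitation-ratio index, and
time-lapse growth tracking. Because every analysis can be exercised against
scenes with known ground truth, the package doubles as a parameter-recovery
test bed for the analysis code itself.

## The forward model

A scene assigns each pixel an expected signal rate. For a fluorophore held
at molar concentration $c$ the per-channel rate is

$$
S_\text{ch} = k \, c \, f_\text{sat}(c)\;
\varepsilon_\text{exc}\, P(d)\;
\sum_\lambda w_\lambda\, T(\lambda)\, Q_\text{ch}(\lambda),
$$

where $k$ is a brightness constant in counts·M⁻¹·ms⁻¹ at unit drive,
$\varepsilon_\text{exc} \in [0,1]$ is the excitation efficiency of the
selected LED channel, $P(d)$ is the LED's monotone power-versus-drive map
(linear by default, $P(0)=0$, $P(1)=1$), $w_\lambda$ are the emission-line
weights (summing to 1), $T$ the filter transmission and $Q_\text{ch}$ the
camera's per-channel relative quantum efficiency. Detector counts are

$$
\text{counts} = \operatorname{clip}\bigl(b_\text{ch} + g\,S_\text{ch}\,t\,
V(x,y) + \text{noise},\; 0,\; 2^{B}-1\bigr)
$$

with exposure $t$ (ms), gain $g$, per-channel black level $b_\text{ch}$,
illumination field $V$ and bit depth $B$ (default 8; 16 supported for
headroom, e.g. gels).

**Inner-filter roll-off.** Dilution series flatten at high concentration.
Rather than model quenching we use the phenomenological inner-filter factor

$$
f_\text{sat}(c) = \frac{1 - 10^{-\varepsilon \ell c}}{\varepsilon \ell c \ln 10},
$$

which is strictly decreasing in $c$ and tends to 1 as $c \to 0$ (a series
expansion is used below $\varepsilon\ell c = 10^{-9}$ to avoid
cancellation). The FITC preset uses $\varepsilon\ell = 22500\ \text{M}^{-1}$
— a molar absorptivity of 75 000 M⁻¹cm⁻¹ over a 0.3 cm path, typical of
200 µL in a PCR well. The real-device literature gives no value; this one
was fixed once and is a named, overridable parameter.

**Ideal step filters and discrete emission lines.** Only cut-on wavelengths
(long-pass, 435–695 nm set) and band-pass windows are known for the
hardware, so transmission is modeled as 0/1 and emitters as weighted line
spectra. This keeps every spectral computation testable in closed form —
e.g. band reconstruction telescopes exactly.

**Noise.** Gaussian read noise per channel, optional Poisson shot noise on
the amplified signal, both clipped to the count range. Dark frames are thus
draws from a zero-clipped Gaussian, whose closed-form moments
(`clipped_normal_moments()`) and their numerical inverse
(`match_clipped_normal()`) let a camera be moment-matched to published
dark-frame statistics. Every stochastic operation takes an explicit seed;
`render_sweep()` derives per-frame seeds as `seed + index` (1-based).

**Camera spectral response.** Gaussian relative-QE curves peaking at 610,
540 and 465 nm (SD 45/40/35 nm) stand in for an unpublished sensor
response. They are only required to be smooth, peaked and overlapping; all
quantitative tests either cancel the QE factor or compute expectations
through the same documented curves.

## Conventions and numerical choices

* Pixels are 0-based, row-major, with centers at integer coordinates;
  region boxes are half-open. Images are floats in detector counts;
  quantization happens only at file write (PNG 8-bit, TIFF 8/16-bit).
* Grayscale uses Rec.601 luma weights (0.299, 0.587, 0.114), the common
  default of consumer-camera conversions; the weights are arguments
  everywhere they appear.
* Stack statistics use the population (divide-by-N) standard deviation and
  pool spatial and temporal variation — published dark-frame summaries do
  not distinguish the two, and the pooled form is what a stack of frames
  actually yields.
* Line profiles sample by bilinear interpolation at `L / ceiling(L)` px
  spacing (both endpoints included), so reversing the endpoints exactly
  reverses the profile.
* The red LED channel is treated as one 630 nm channel throughout; vendor
  sheets that quote 620 nm for the same part are folded into it.

## Calibration procedures

**Black level.** `black_level()` pools a dark stack per channel and flags
"calibration needed" above a 1-count mean threshold. The
`preset_dark_camera()` configuration inverts the clipped-normal moments for
the published means [0.50, 0.36, 0.57] and SDs [0.84, 0.68, 0.87].

**Color accuracy.** CIE76 ΔE after sRGB→Lab (D65) via
`grDevices::convertColor`; black versus white scores exactly 100 (pure L*).
CIEDE2000 would be a straightforward extension but CIE76 suffices for
chart-level agreement checks.

**Distortion.** A dot-grid chart is detected (low-threshold connected
components, intensity-weighted centroids), integer lattice indices are
assigned from the median nearest-neighbor pitch, and
$r' = \alpha\rho + \beta\rho^3$ is fit about the image center, giving
$k_1 = \beta/\alpha^3$ in the classical $r' = r(1 + k_1 r^2)$ model.
Only the $k_1$ term is modeled; the principal point is assumed at the image
center (true for the rendered charts; approximately true for a centered
chart photograph). $|k_1| < 10^{-8}\,\text{px}^{-2}$ classifies as
distortion-free.

**Resolution.** The 1951 USAF target assigns element frequencies
$2^{g + (e-1)/6}$ lp/mm. Bars are rendered with exact subpixel coverage;
`usaf_resolution()` measures Michelson contrast
$(I_\max - I_\min)/(I_\max + I_\min)$ on a finely sampled profile across
each element's three bars and walks from coarse to fine, stopping at the
first element below the contrast threshold (default 0.1, a Rayleigh-like
and configurable cut; the hardware literature states none). For a Gaussian
blur of SD $\sigma$ the square-wave fundamental attenuates as
$(4/\pi)e^{-2\pi^2\sigma^2 f^2}$, crossing contrast 0.1 near 12 lp/mm at
$\sigma = 30$ µm — the rendered-and-measured pipeline reports the nearest
element below that, and one line is half a line pair, so
`lp_per_mm_to_um()` is simply $500/f$.

## Plate quantification and flatness

Grid detection refines nominal lattice centers by local intensity centroid
within a quarter pitch; without a layout, pitch comes from profile
autocorrelation and phase from comb matching (8 × 12 assumed). Wells with
no signal mass fall back to the lattice position — a dilution plate is
mostly empty by design — while centroids that run away on more than 10% of
wells reject the grid. The well statistic is the mean over a disk of 0.8
well radii (avoiding wall reflections); background subtraction (median of
a 1.2–1.5 r annulus, floored at 0) is the default for dilution plates and
off for flatness, which reports raw variation. Flatness is summarized as
the maximum absolute per-well percent deviation from the plate mean — the
deviations sum to zero by construction. `flat_field_correct()` divides by
a normalized field estimate.

The flatness preset fixes what the study conditions leave open: brightness
is set so well means sit mid-scale (~150 counts) at the 10 ms flatness
exposure, and the per-pixel read noise is derived from the target per-well
SNR of 200 after accounting for shot noise averaged over the measurement
disk.

## Exposure sweeps, LOD and sensor calibration

`build_curves()` reduces a sweep to mean/SD/n per concentration per
exposure, with blanks (concentration-0 wells) kept per exposure. The
detection threshold is blank mean + k·SD (k = 3 by default; the hardware
literature states a detection range but no rule). The LOD is the smallest
detected concentration over all exposures under *monotone closure*: every
larger tested concentration must itself be detected somewhere, so an
isolated noise-triggered detection below an undetected step cannot set the
LOD. The implementation is tested for exact agreement with a brute-force
enumeration oracle on random curves.

Dynamic range at one exposure runs from the smallest detected concentration
to the largest whose mean stays below 0.9 of full scale (the saturation
guard is configurable; "unsaturated" has no published cut). The
exposure recommendation maximizes the count of target-range concentrations
inside that window, ties to the shorter exposure — one defensible
formalization of the qualitative "pick the exposure that fits your
concentration range" guidance, and labeled as such.

Nanosensor-style calibration fits the four-parameter logistic
$y = \text{bottom} + (\text{top}-\text{bottom})/(1 + 10^{\,s(\log_{10}\text{EC}_{50} - x)})$
by Levenberg–Marquardt, initialized from the series min/max, the
mid-response crossing and the trend sign.

## Gels, spectra, growth

Lane profiles are per-row means over a user-supplied lane box (manual lane
cropping mirrors practice; automatic lane finding is out of scope), with a
rolling-minimum background (window 50 px) floored at 0. Bands are local
maxima with prominence ≥ 5% of the profile range; areas are trapezoidal
integrals between flanking minima. Note that widening a lane box with
background columns rescales profile amplitude by the width ratio (per-row
averaging) while leaving band positions and relative areas unchanged.
Migration follows the semilog model $\text{position} = a - b\log_{10}(\text{bp})$.

Long-pass series must be nonincreasing in cut-on; real noise violates this,
so `channel_response()` applies nonincreasing isotonic regression and flags
adjusted points rather than erroring. Band reconstruction takes telescoping
differences, floors at 0, and conserves the first-cut-on signal exactly on
monotone input.

The anthocyanin index is implemented as the log excitation ratio
$\ln\bigl((F_\text{red exc} + \varepsilon)/(F_\text{green exc} +
\varepsilon)\bigr)$ with $\varepsilon = 0.5$ counts guarding near-black
pixels, matching the two acquisition conditions used for plant imaging
(520 nm versus 630 nm excitation, both through a 665 nm long-pass). The
exact published variant of the index is not recoverable from the hardware
literature; the formula is documented and pluggable.

Specimen segmentation is Otsu's threshold on the gray channel, largest
connected component, holes filled; growth is the least-squares slope of
ln(area) versus time (exponential model; a linear option exists because no
growth model is published for the reference specimens).

## What the generator does and does not emulate

The synthetic scenes reproduce the geometry, signal chain, saturation and
noise character of the real instrument's experiments: decade dilution
series with triplicates and blanks, a uniform flatness plate under 2%
radial vignetting, three-bar resolution charts with optical blur, the
24-patch color chart, dot-grid distortion charts, multi-lane band ladders,
line-spectrum emitters behind the eleven-filter long-pass set, and a
growing elliptical specimen. They do **not** emulate Bayer mosaicing and
demosaicing artifacts, lens PSFs beyond Gaussian blur, stray light and
diffuser non-uniformity beyond the smooth radial field, well meniscus and
edge reflections, autofluorescent backgrounds, or biological shape
variability. Passing tests therefore demonstrate that the *analysis*
recovers known truth under a faithful signal model — not that the physical
instrument meets any specification.

## Problem sizes and determinism

The test suite and the acceptance script run the full pipelines at
deliberately modest sizes chosen to exercise every code path: 96-well
plates at 40 px pitch (360 × 520 px frames), six-exposure sweeps,
resolution charts of groups 0–3 (~1600 × 590 px), four-lane gels, eleven
filter frames, ten-day growth series, and dark stacks up to 10 × 1000 ×
1000 px for the black-level estimate (Monte-Carlo SE ≈ 3 × 10⁻⁴ counts).
All stochastic paths are seeded; noise-free rendering is bitwise
deterministic.

## Known limitations

* Grid autodetection assumes the default 8 × 12 format and near-axis-aligned
  plates; rotated plates need an explicit layout.
* The distortion fit assumes a centered chart and a single radial term.
* Absolute radiometry (counts → moles) is out of scope; brightness
  constants are instrument-relative.
* DNG/RAW ingestion, demosaicing, ICC color management and hardware drivers
  are out of scope — the package consumes and produces demosaiced RGB.
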