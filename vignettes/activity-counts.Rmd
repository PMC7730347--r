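---
title: "Activity counts from raw acceleration: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity counts from raw acceleration: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wearcounts)
```

## The quantity being computed

An *activity count* is a scaled, thresholded, epoch-summed magnitude of
band-passed acceleration, used across rehabilitation and physical-activity
research as a proxy for movement intensity. The unit is historical (1 count
= 0.001664 g) and only meaningful relative to the published cut-points that
map counts per minute to intensity categories; the value of an open
implementation is that every stage is inspectable and adjustable.

For each axis the pipeline applies, in order: band-pass filter →
rectification → saturation at 2.13 g → deadband at 0.068 g → scaling by
1/0.001664 counts per g → gain → 1-s epoch aggregation (epoch sum divided
by the sampling rate, i.e. the mean count per second). The per-epoch axis
counts $s_{x,i}, s_{y,i}, s_{z,i}$ combine as
$\mathrm{VM3}_i = \sqrt{s_{x,i}^2+s_{y,i}^2+s_{z,i}^2}$.

### On rectification

Descriptions of count algorithms often omit the rectification step, but it
is load-bearing: the band-passed signal is zero-mean, so amplitude
thresholds and nonnegative epoch sums only make sense on $|y_n|$. We place
full-wave rectification between the filter and the saturation stage, as the
open-source count algorithm this design builds on does. It can be disabled
(`pipeline_config(rectify = FALSE)`) for experimentation; with it off, the
deadband zeroes *negative* excursions entirely and counts lose their
meaning — the switch exists to make that visible, not for production use.

### Units

All thresholds are stated in g and filtering is performed in g; m/s²
input is converted at ingest. The conversion constant defaults to
9.8 m/s² per g rather than 9.81, because the pipeline's printed constant
pairs (0.068 g = 0.6664 m/s², 0.001664 g = 0.0163072 m/s²,
2.13 g = 20.874 m/s²) are exact only at 9.8. It is configurable
(`pipeline_config(g_to_ms2 = )`).

## The two filter variants

Movement content of voluntary activity concentrates roughly in
0.3–1.6 Hz; gravity contributes DC and posture drift below that band, and
artifacts (tremor at 4–6 Hz, impacts, sensor noise) above it.

**Modifiable bandwidth.** A 4th-order analog Butterworth band-pass with
half-power cutoffs at 0.305 and 1.615 Hz by default. "4th order" here means
total denominator degree 4 (an order-2 low-pass prototype transformed to a
band-pass); some design tools quote the prototype order, which doubles the
degree, so the order is exposed as a parameter (`order = 8` reproduces that
convention). We treat "−3 dB" as the half-power point, $-10\log_{10}2
\approx -3.0103$ dB, the Butterworth design convention. Both cutoffs are
plain arguments, which is the point of this variant: narrowing the band
(e.g. `high_hz = 1.0`) demonstrably removes tremor-attributable counts
(tested with a 5 Hz overlay).

**Fixed bandwidth.** An 8th-order continuous transfer function produced by
`fit_bandpass_to_reference()` against a packaged reference-response table,
mimicking the sharper skirts of the count filter used by commercial
software. The packaged table (`inst/extdata/synthetic_reference_response.csv`)
is a *synthetic* stand-in — the magnitude response of a known stable
8th-order band-pass built in `scripts/make_reference_response.R` — because
the commercial filter's response is not ours to redistribute. The fitting
procedure, not the particular coefficients, is the deliverable: point the
fitter at your own measured table to replicate a specific device.

### Fitting procedure

The fit searches over second-order sections: $m = \mathrm{order}/2$ zeros
at the origin and $m$ denominator factors $s^2 + 2\zeta_k\omega_k s +
\omega_k^2$, parameterized by $(\log\omega_k, \log\zeta_k, \log g)$ so that
every candidate is stable by construction (no projection or rejection step
is needed). The objective is the mean squared dB-magnitude error on the
reference grid. A small differential-evolution search (DE/rand/1/bin,
population $10d$ for $d$ parameters, up to 200 generations, stagnation
tolerance $10^{-10}$) provides the global stage, seeded with a Butterworth
candidate constructed from the reference's measured half-power band; BFGS
refines the best member. Results are bit-reproducible for a fixed seed.

When the reference describes a *discrete* filter, pass `fs` and each
candidate is matched through its bilinear discretization. This uses the
identity $H_d(e^{i\omega}) = H_a\!\big(2 f_s \tfrac{z-1}{z+1}\big)$: the
discretized response is evaluated by warping the evaluation points, which
is exact and avoids a polynomial transformation per objective call. The
default fixed filter is fitted this way at 30 Hz (matching how such
reference filters are characterized), with a fixed internal seed, and
cached for the session; the fit takes a few seconds.

### Discretization

Analog designs are discretized with the plain bilinear (trapezoidal)
transform, no pre-warping: with passbands below 2 Hz and rates of
30–100 Hz, warping is negligible where it matters. Measured on the default
modifiable filter, the analog and digital magnitudes agree within 0.1 dB
across the passband at 30 Hz and across 0.05–3 Hz at 100 Hz; at 30 Hz the
deviation grows on the upper skirt (≈0.12 dB at 1.615 Hz, ≈0.6 dB at 3 Hz)
purely from frequency warping. `discretize(..., prewarp_hz = )` matches the
response exactly at one chosen frequency if that trade-off is preferred.
Rates below 10× the upper band edge are rejected rather than warped badly.

Filtering is causal (direct form, zero initial conditions), matching a
streaming count device; this leaves a start-up transient of a few seconds,
which is why tests and examples discard a ~10-epoch settling prefix when
asserting steady-state values. Zero-phase forward–backward filtering is
available (`bidirectional = TRUE`) but off by default.

## Classification

Cut-point scales are ordered categories with counts-per-minute lower
bounds, encoded as half-open intervals. The shipped Freedson Adult VM3
scale is Light $[0, 2960)$, Moderate $[2960, 6167)$, Vigorous
$[6167, 9643)$, Very vigorous $[9643, \infty)$ — equivalent to the
published integer ranges, while also placing the non-integer
counts-per-minute values that rescaled windows produce.

**Discrete method**: back-to-back 60-s blocks from the start of the
series, block cpm = sum of its sixty 1-s VM3 counts, trailing partial
minute dropped. This matches commercial exports but makes the category
percentages depend on how activity aligns with the epoch grid.

**Continuous method**: one window per second, the half-open 60-epoch span
$[i-30, i+30)$. We read "30 preceding and 30 following seconds" as a
60-s window so that each window is exactly one minute; the alternative
61-s reading (center second plus 30 each side) is available via
`window_s = 61`. Boundary windows are clipped to the series and rescaled
by $60/\text{length}$, which keeps them on the cpm scale and yields
exactly one window per second — 180 windows for a 3-min series — rather
than zero-padding, which would deflate boundary intensities. A constant
series classifies identically under both methods; a time-shifted activity
changes the discrete percentages but not the continuous ones (shifts
implemented by same-level padding leave interior window contents
unchanged), which is the motivation for the continuous method.

## Agreement statistics

`agreement(a, b)` compares a comparator `b` against a reference `a`:
Pearson and Spearman correlation (average ranks on ties), relative
difference of totals $100(\Sigma b - \Sigma a)/\Sigma a$, Bland–Altman
mean difference with $\pm 1.96\,\mathrm{SD}$ limits of agreement and the
count/percentage of points outside them, and an OLS regression of
$|b-a|$ on $(a+b)/2$ to detect intensity-dependent error. The sign
convention is comparator minus reference throughout. Zero-variance inputs
flag the report rather than erroring, since constant segments are common
in real recordings. `reaggregate()` moves 1-s series to 10/30/60-s epochs
for scale-dependent comparisons.

## The synthetic generator

`gen_sinusoid()`, `gen_profile()` and `gen_tremor_overlay()` emulate the
features the pipeline responds to: in-band sinusoidal movement
(0.3–1.6 Hz), a piecewise-constant activity profile across segments,
white Gaussian noise, gravity as +1 g DC on the z axis (the band-pass
removes DC, so the placement is arbitrary and fixed for reproducibility),
out-of-band tremor overlays, and clipping to the ±8 g range of typical
wrist-worn sensors. Defaults mirror common study conditions: 30 or 100 Hz
sampling, movement amplitudes of 0.05–1.2 g, noise SD around 0.02 g.

What the generator does *not* emulate: biomechanically realistic movement
spectra (real activity is broadband and non-stationary), device-specific
quantization and timing jitter, non-wear periods, and posture changes.
Passing tests therefore establish that the pipeline computes its defined
transform correctly and responds to band-limited content as designed —
not that counts from any particular commercial device are reproduced
bit-for-bit on human recordings, which requires those devices' recordings
and exports.

## Numerical choices and problem sizes

- Stability is verified by pole location on every constructed filter
  (left half-plane for analog, open unit disk for digital).
- The deadband keeps values exactly equal to the threshold; it zeroes
  rather than subtracts.
- Quantization (floor to integer counts) is off by default, preserving
  the continuous mean count per second; enable it to emulate
  integer-count devices.
- Trailing samples or seconds that do not fill an epoch/minute are
  dropped, and the CLI logs how many.
- Test and example signals are 10 s–4 min at 30–100 Hz, and oracle
  cross-checks (naive loop reimplementations of the pipeline, window
  slicing, agreement formulas) run on a few hundred samples — small
  enough to be exhaustive, large enough to include settling transients
  and epoch boundaries. The Bland–Altman coverage property uses
  n = 10,000 Gaussian differences.

## Known limitations

- The fixed-bandwidth default reproduces a synthetic reference, not any
  particular commercial filter; users targeting a specific device must
  supply a measured response table.
- Counts are not energy expenditure: no MET conversion, non-wear
  detection or step counting is included.
- Sampling rates below 30 Hz are rejected rather than resampled.
- The continuous classifier's boundary rescaling slightly amplifies
  noise in the first and last 30 s of very short recordings.
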