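---
title: "How peakmap measures events and builds maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How peakmap measures events and builds maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakmap)
```

`peakmap` quantifies trains of stereotyped physiological events — action
potentials, calcium transients, contraction twitches — in single traces
(XT data) and, pixel by pixel, in image stacks (XYT data such as cardiac
optical mapping or confocal calcium recordings).  This vignette explains
the model behind each measurement, the tunable parameters and their
defaults, what the built-in simulator does and does not emulate, and the
design decisions taken where more than one reasonable construction exists.

## Detection: prominence against the global range

A candidate event is a local extremum of the trace; a plateau of tied
samples counts once, at its first sample.  Candidates are ranked by
**topographic prominence**: the height of the apex above the higher of the
two key saddles that separate it from higher terrain, with the trace ends
treated as open terrain.  A candidate is kept when its prominence exceeds

> `sensitivity_percent / 100 × (global maximum − global minimum)`.

The denominator is deliberately the *whole-trace* range, not a local one:
the sensitivity setting then has the same meaning everywhere in the
recording, and a single number cleanly separates physiology from noise.
Prominence itself is parameter-free — no window length needs tuning, which
matters when event widths vary by an order of magnitude between an action
potential upstroke and a slow calcium wave.

Negative-going events (e.g. inverted dye signals) run the identical
procedure on the negated trace.  By convention their amplitude, area and
rising slope are reported positive; `apex_value` and `baseline` keep the
original sign.

Two practical aids, both off by default:

* `smooth_window` — a boxcar-smoothed copy used *only* for the detection
  decision.  The sensitivity test runs on the smoothed copy (so noise
  spikes whose raw prominence would pass are genuinely suppressed), then
  the apex is relocated to the raw maximum of the smoothed peak's top
  (the region within half its prominence of the apex) and the reported
  prominence is re-measured on the raw trace.
* `min_separation` — apexes closer in time than this are merged, keeping
  the larger prominence; this prevents double counting on noisy upstrokes.

Event boundaries: the right boundary of an event is the midpoint to the
next apex (or the trace end); the left boundary is found by an onset
search — the last sample before the apex that lies within 5% of the
preceding segment's floor.  The onset search, rather than a bare midpoint,
leaves a genuine quiet segment between events for the baseline estimate
and guarantees that threshold and width levels are crossed inside the
event's bounds even for pixels that activate immediately.

### Sub-sample apex time

`apex_index` is always the raw extremum sample.  `apex_time` is, by
default (`apex_refine = TRUE`), the vertex of a quadratic fitted to the
±4 samples around the apex — the standard sub-sample peak interpolation.
On flat-topped events the raw argmax wanders by a sample or two under a
few percent of noise; the quadratic vertex roughly halves that error and
is exact for noiseless symmetric peaks.  The fit half-window of 4 samples
balances the cubic-term bias on asymmetric peaks (which grows with the
window) against the noise variance of the vertex (which shrinks with it).
Plateaus are never refined: a tied top means the extremum is a region and
the first-sample tie-break stands.

## Per-event parameters

All measurements are made on the sign-adjusted raw trace.  With baseline
`b` and amplitude `A = apex − b`:

* **Baseline** — median of the quiet segment preceding the event (between
  the previous event's right boundary and this event's left boundary),
  using the later half of that segment, which is closest to the onset and
  least contaminated by the previous event's decay tail.  If fewer than
  3 samples are available the fall-back is the pre-apex minimum.  The
  median is robust to both noise and stray spikes; a per-event baseline
  (rather than one global value) tolerates drift.
* **Threshold / Time2Pk** — the threshold marker is the rising crossing of
  `b + threshold_fraction·A` (default 0.10); time-to-peak runs from this
  crossing to the apex, matching common cardiac usage where the "foot" of
  the upstroke starts the clock.
* **Fractional widths** — FWHM and FW10 are the widths at 50% and 10% of
  `A`; for an action potential these are APD50 and APD90.  The rising
  crossing is the *last* upward crossing before the apex, the falling one
  the *first* downward crossing after it, each interpolated linearly
  between the bracketing samples so that widths do not quantize to the
  sampling step.
* **Area** — trapezoidal integral of `signal − b` between the two
  threshold crossings (the interpolated crossing points are used as the
  end nodes).
* **Max slopes** — extremal two-point finite differences over the rise and
  decay segments, reported with the midpoint time of the winning pair;
  first pair wins ties.
* **Decay constant** — `b + A·exp(−(t − t₀)/τ)` is fitted to the decay
  restricted to `decay_fit_range` (default 90% down to 10% of `A`).  A
  log-linear regression of `log(signal − b)` initializes τ; a
  Levenberg–Marquardt refinement (via `minpack.lm`) follows, and if it
  fails to converge the log-linear estimate is kept.  Fewer than 5 usable
  samples, or non-positive residuals, flag the fit invalid rather than
  producing a number.

### Crossings on the monotone trend

On a noisy shallow decay the literal "first sample pair that crosses the
level" is a biased estimator: the first *noise excursion* below the level
always comes earlier than the trend crossing, so widths shrink
systematically (around −10% for FW10 at 2% noise in our simulations).
The rise and decay of a unimodal event are monotone by definition, so the
package locates crossings on the **isotonic (monotone) regression** of
each phase — non-decreasing for the rise, non-increasing for the decay —
and then interpolates linearly.  Isotonic regression is parameter-free
and is the identity on noiseless data, so clean signals are measured
exactly as the literal rule would.  The apex, amplitude, slopes, area
integrand and τ fit all remain on the raw samples.

Every sub-parameter can individually be invalid (`NA`) — a truncated
event whose level is never re-crossed, a too-short decay — while the
event record itself is always returned.

## Stacks: the XT engine per pixel

A stack is analyzed by running the identical trace engine on every in-mask
pixel (`analyze_stack()`); nothing is ever interpolated into pixels where
nothing was detected.  Optional stack-level pre-smoothing (spatial
Gaussian `spatial_sigma`, temporal boxcar `temporal_window`, both off by
default) can be applied for very noisy recordings.

Coordinates are row-major with the origin at the top-left pixel, x
rightward along columns, y downward along rows; vectors are reported in
this frame and only flipped for display.

* **Isochronal map** — one activation time per pixel: the 50% upstroke
  crossing by default (robust to noise because the upstroke is the
  steepest part of the event), or the time of maximal dV/dt.  The earliest
  valid pixel defines delay zero; we prefer this to an external stimulus
  reference because it requires no extra channel, and the subtracted
  constant is kept as `t0`.  At pixels with several events one selected
  event is used (default: the first).
* **Vector field** — for every pixel, the activation times in the
  surrounding `(2r+1)²` window (default r = 2) are fitted with a plane
  `t(x,y) = a + g·(x,y)`; the velocity is `g/|g|²`, the standard inversion
  of the activation-time gradient.  Windows are invalid with fewer than
  60% valid pixels (or < 3), with a gradient below `min_gradient`
  (quasi-simultaneous activation has no finite velocity — a flat map
  yields *no* vectors rather than wild ones), or with an RMS plane
  residual above `residual_cap`.  With a physical `pixel_pitch` speeds
  come out in length per time unit, otherwise in pixels per time unit.
* **Parameter maps** — the arithmetic mean of the chosen parameter over
  each pixel's valid events, with the per-pixel event count reported; a
  pixel with a single event carries that event's value exactly.

## The simulator

The simulator is the package's source of ground truth, and doubles as a
way to rehearse an analysis before trusting it on real data.  Two
waveforms expose every parameter the analyzer measures:

* `transient` — `A·(exp(−t/τ_decay) − exp(−t/τ_rise))`, normalized so the
  maximum is exactly `A`; apex time in closed form.  The shape of a
  calcium transient or twitch.
* `ap_plateau` — sigmoidal upstroke (time constant `τ_rise`, centred at
  `5·τ_rise`), sustained plateau, exponential repolarization; an action
  potential surrogate whose FWHM/FW10 play the role of APD50/APD90.

Trains add timing jitter, amplitude jitter, baseline level, linear drift
and iid Gaussian noise; waves delay the waveform by an analytic activation
field (planar at any angle, or radial), optionally with linear parameter
gradients across the field of view.  Ground-truth widths are obtained by
root-finding on the *continuous* waveform, never from the sampled signal,
so recovery errors measure the analyzer, not the grid.  All generators
require a seed and are bit-reproducible; the caller's RNG state is saved
and restored.

What the simulator does **not** emulate: photon shot noise (noise is
Gaussian and signal-independent), motion artifacts, photobleaching,
spatial blur from optics, curved or colliding wavefronts, and arrhythmic
dynamics.  Passing the validation grid therefore demonstrates correctness
of the measurement pipeline under controlled conditions, not robustness to
every artifact of real recordings.

## Validation studies and the numbers they produce

`recovery_study()` simulates trains over amplitudes {0.5, 1, 2} ×
τ_decay {25, 50, 100} ms × noise {0, 2, 5}% of amplitude (τ_rise 5 ms,
period 500 ms, dt 1 ms, 5 events, 20 seeds per cell — sizes chosen to keep
the full grid under a minute on one core) and reports per-event recovery
errors against the analytic truth.  The analysis configuration for the
noisy grid uses `smooth_window = 7` and `min_separation = 125` ms — the
documented knobs any user of noisy data would set.  `velocity_study()`
simulates 64×64 planar waves at 0.1–1.0 px/frame in four directions with
5% noise and reports median speed and angle errors of the recovered vector
fields.  `scripts/acceptance.R` runs both, plus radial-wave checks, the
closed-form Gaussian FWHM, the averaging rule and determinism checks, and
writes all quantities as JSON.

## Numerical choices and degenerate inputs

* Level crossings: linear interpolation between bracketing samples;
  sub-sample accuracy assumed meaningful only because crossings are taken
  on the monotone phase trend.
* τ fit: log-linear initialization, `nlsLM` refinement capped at 50
  iterations, lower bounds A ≥ 0, τ > 0; refinement failure falls back to
  the initializer rather than invalidating the event.
* Ties: plateau apexes take the first sample; tied extremal slopes take
  the first pair; merging keeps the larger prominence.
* A constant trace has zero range — no events, not an error.  An empty
  analysis yields a table with zero rows and the full header.
* Uniform sampling is enforced to a relative step tolerance of 1e-6;
  non-finite samples are rejected at load with their row and column.
* Maps are written as uncompressed 32-bit float TIFF in native units with
  NaN marking invalid pixels — a format every scientific TIFF reader
  ingests; values survive the round trip bit-exactly after the single
  float32 quantization.  CSV numbers carry 9 significant digits.

## Known limitations

* Overlapping events share boundaries at the midpoint/valley between
  apexes; severely fused events (period shorter than the waveform's 1%
  footprint — flagged by the simulator) bias widths and τ.
* The baseline is estimated per event from the preceding quiet segment; a
  baseline that drifts *within* one event is not modelled.
* Amplitude is read at the raw apex sample and is therefore biased upward
  by the expected maximum of the noise near the peak (≈ +6% at 5% noise);
  median recovery across realistic noise levels stays within a few
  percent.
* Vector fields assume a locally planar wavefront across the fit window;
  strongly curved fronts (near a radial origin) deviate within the window
  radius of the origin.
* The CLI reads delimited text and single-channel grayscale TIFF only;
  vendor acquisition formats must be converted upstream.
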