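---
title: "Extracting vital signs from a moving subject with one CW Doppler radar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting vital signs from a moving subject with one CW Doppler radar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radvital)
```

## The problem and the signal model

A continuous-wave Doppler radar transmits a single tone and receives its
reflection from the subject's torso. Target displacement $x(t)$
phase-modulates the reflection; after quadrature down-conversion the
baseband pair is

$$B_I(n) = \cos\theta(n), \quad B_Q(n) = \sin\theta(n), \quad
\theta(n) = \frac{4\pi d_0}{\lambda} + \frac{4\pi x(n)}{\lambda} + \phi,$$

so one wavelength of round-trip path change sweeps the phase through
$4\pi$. At 10 GHz ($\lambda \approx 29.98$ mm) the millimetre-scale
chest wall produces a fraction of a radian, while body motion of tens of
centimetres wraps the phase many times over. The displacement model used
throughout the package is

$$x(t) = m_r \sin(2\pi f_r t + \phi_0) + m_h \sin(2\pi f_h t + \phi_0)
  \pm v\,t,$$

respiration plus heartbeat riding on a constant-velocity translation
whose sign is the motion direction. The generator defaults
(`motion_params()`) are the validation conditions: $m_r = 3$ mm at
$f_r = 0.4$ Hz, $m_h = 1$ mm at $f_h = 1.3$ Hz, $v = 30$ mm/s, sampled
at $f_s = 100$ Hz for 5 s ($L = 500$ samples). Respiration in adults
lies below 0.6 Hz and heartbeat within 0.8–3 Hz; these are the default
peak-picking bands.

## Phase demodulation (DACM)

`dacm_phase()` accumulates
$\{B_I \Delta B_Q - \Delta B_I B_Q\}/(B_I^2+B_Q^2)$ from the second
sample on, with $\varphi(1) = 0$: the first sample has no predecessor,
and a relative phase is all that rate estimation needs. The constant
$4\pi d_0/\lambda + \phi$ is unobservable, which is why
`phase_to_displacement()` treats the nominal-distance shift as an
optional reporting offset rather than an estimate. A denominator floor
($10^{-12}$) converts numerically dead samples into an explicit error
naming the index instead of propagating `Inf`.

For a unit-amplitude pair each increment equals $\sin\Delta\theta$
exactly, so the accumulator carries a cubic truncation error per step.
Two consequences, both verified in the test-suite:

* For stationary subjects (oscillatory $\Delta\theta$) the error largely
  cancels; the synth–demod round trip recovers the displacement within
  0.05 mm (measured ~0.0013 mm on the default amplitudes).
* Along a steady 30 mm/s ramp the truncation accumulates coherently into
  a smooth, trend-like bias of about 0.25 mm over 5 s at $f_s = 100$ Hz
  (halving the step quarters it). This bias is absorbed by the
  polynomial reference in the next stage and never reaches the rate
  estimates, but it does mean phase-faithful displacement recovery below
  ~0.1 mm should not be expected while the subject translates quickly.

## RBM cancellation: polynomial reference + LMS

`fit_polynomial()` builds the body-motion reference. The fit is linear
least squares on an index variable centred and rescaled to $[-1, 1]$:
raw sample indices up to several hundred raised to the fourth or fifth
power make the normal equations hopeless in double precision, while the
rescaled basis is well-conditioned for all supported orders (0–5);
fitted values are basis-independent. Orders 3–4 are the validated
choices for a constant-velocity excursion plus vital ripple; the
pipeline warns outside that set.

`lms_anc()` then adapts, per sample,
$y(n) = \mathbf w^T \mathbf x_f(n)$, $z(n) = \hat x(n) - y(n)$,
$\mathbf w \leftarrow \mathbf w + 2\mu\,\mathbf x_f(n) z(n)$, over a
lagged, zero-padded window of the reference (8 taps by default),
sweeping the record repeatedly with weights carried over and stopping
when the sweep-level mean of $z^2$ improves by less than $10^{-6}$
(relative) — the operational reading of "stop at the minimum of the
residual mean square", treated as a convergence criterion rather than a
fixed sweep count.

The step size deserves care. The reference is normalised to unit power
internally, so one $\mu$ works across amplitude scales, but $\mu$ also
sets the *tracking bandwidth* of the filter: with $\mu$ large enough
that the weight time constant $1/(2\mu \cdot \text{taps})$ drops below a
respiration period (250 samples here), the filter follows the
oscillation within a sweep and cancels the very signal the stage is
meant to preserve — the residual mean square then falls *below* the
vital-sign power, a useful diagnostic of over-adaptation. The default
$\mu = 5\times10^{-5}$ keeps the time constant near 1250 samples:
quasi-static within a record, converging across sweeps to the static
Wiener solution (the single-tap weight matches the closed-form solution
within 1%, a test-suite invariant). The sweep cap (500) exists only so
the stopping rule has room to trigger; on the default fixture it stops
after ~36 sweeps.

Two practical notes. First, because the lagged window is zero-padded,
the filter start-up sees a truncated reference; records should be
re-referenced so they start near zero displacement (the segmented
pipeline does this per window), otherwise each sweep begins with a large
error kick. Second, with a multi-tap filter the small-eigenvalue lag
modes converge impractically slowly, so cancellation depth on a pure
ramp saturates around 0.1–1% of the excursion; a single-tap
configuration reaches numerical depth ($<10^{-6}$) if that matters.

### Which fit order?

Over a 5-s window the 0.4 Hz respiration completes exactly two cycles.
With the default extremum phasing it is even about the window centre, a
symmetry shared by the quartic basis term: once the canceller converges,
a 4th- or 5th-order reference absorbs a substantial part of the
respiration and distorts its peak by ~0.18 Hz, whereas orders 1–3 leave
it intact (measured RR peak errors of 3.6, 1.0, 0.2 mHz for orders
1–3). The package therefore defaults to order 3 — enough flexibility
for mildly non-constant velocity, no even-quartic overlap with the
respiration — and the order-3 fit measurably beats the order-1 fit on
peak localisation. We note this ranking is a property of the converged
minimum-mean-square solution under this window/rate geometry; an
under-converged canceller shuffles it.

## Spectral estimation and its phase convention

`ndct()` evaluates $X[k] = 2\sum_{n=0}^{L-1} z(n)\cos(2\pi kn/M)$, fast,
as twice the real part of the $M$-point zero-padded DFT (algebraically
identical; the identity against the direct $O(LM)$ summation to
$10^{-9}$ relative is a test invariant). $M = 2^{17}$ by default: zero
padding refines the peak grid to $f_s/M \approx 0.76$ mHz without adding
resolution; below $M = 2^{11}$ grid quantisation visibly degrades the
recovered rates (a test asserts the $2^9$ vs $2^{17}$ ordering), while
beyond $2^{13}$ the gain is marginal. Magnitudes are reported so that
peak locations are sign-invariant.

The cosine projection is *not* phase-blind: it is the spectrum of the
even extension of the record about its first sample. A component at an
extremum of its cycle at $n = 0$ extends coherently over $2L$ samples —
hence a main lobe about half the FFT's width (verified at half-maximum
on the default fixture: 0.123 vs 0.271 Hz) and sharper localisation. A
component a quarter-cycle off extends antisymmetrically and *cancels*:
the projection has a null at the tone and twin lobes ±0.1 Hz away. The
generator's default initial phase ($\phi_0 = \pi/2$, extremum at window
start) is chosen once to place the synthetic components in the
estimator's coherent regime, which is the only convention under which
the published single-radar simulation behaviour (peaks within one grid
bin of the true RR) is reproducible; the phase sensitivity itself is an
inherited property of the transform and is a real limitation for
arbitrary-phase windows.

Residual interference still floors the achievable peak accuracy: on a
5-s window, leakage between components, band edges, and the window-end
discontinuity bias band argmaxes by a few mHz (the HR estimate lands
~5 mHz below 1.3 Hz, −0.4%, comparable to the method's observed
real-data accuracy). Sub-millihertz agreement should only be expected
for components completing an integer number of cycles.

The heartbeat path first applies `highpass_heartbeat()`: a Chebyshev
type-II high-pass run forward and backward (zero phase), with the
smallest order (search over 4–8) whose *zero-phase* magnitude response
gives ≥ 40 dB at 0.7 Hz and ≤ 1 dB deviation at 0.9 Hz — at the default
rate this resolves to order 7 with a 23 dB design stopband, stable in
transfer-function form (pole radius 0.996). Only the band edges are
anchored by the method; family and tolerances are this package's
choices. Edge transients are tamed by odd-reflection padding of one
record length per side.

## Segmentation of back-and-forth motion

`segment_by_direction()` implements: smooth the first difference with a
1-s moving average (the mm-scale vital ripple contributes at most
~6 mm/s to the smoothed derivative, well under the ≥ 20 mm/s trends of
interest, so it cannot flip the sign), take the derivative sign, merge
runs shorter than 2 s into their predecessor (hysteresis against
jitter at turning points), split runs longer than 3.5 s into near-equal
pieces, and label each segment with its majority sign. The duration
defaults target ~3-s parts — short enough for the constant-velocity
assumption, long enough (≥ 3 s) for rate estimation. Segments tile the
record exactly; turning points on synthetic sway records are located
within ~0.15 s.

## The "no signal" flag

A band argmax always exists, so the segmented pipeline refuses to report
a rate unless the peak both stands out of its band (≥ 3× the in-band
median magnitude) and implies a plausible chest-wall amplitude
(≥ 0.15 mm, using peak/L as the amplitude of an extremum-phased
component). The amplitude criterion is what catches a vital-free
translation record in the heartbeat band; a known limitation is that the
canceller's own low-frequency residual (~0.5 mm RMS on a pure-ramp
record) can still imitate a weak breathing peak, so respiration flags
from strongly moving, possibly breath-holding subjects deserve
scepticism.

## What the generator does and does not emulate

Synthetic records reproduce the deterministic structure the method is
built on: exact unit-amplitude quadrature, constant per-segment
velocity, stationary sinusoidal vitals with known phase, optional
seeded additive Gaussian I/Q noise (off by default; the baseband model
itself is noiseless). They do not emulate amplitude modulation of the
returned power, I/Q imbalance or DC offsets (assumed calibrated
upstream), respiratory harmonics and rate variability, limb-motion
Doppler, or clutter. Passing tests therefore demonstrate correctness of
the algorithms under the stated model, not field performance on human
recordings.

## Numerical choices, in one place

* Time origin $t_1 = 0$, 1-based indexing; displacements mm, time s,
  rates Hz.
* Wavelength derived as $c/f$; consistency enforced to $10^{-4}$%.
* DACM denominator floor $10^{-12}$; degenerate samples are errors, not
  `NaN`s.
* Polynomial fits on the $[-1,1]$-rescaled index; coefficients reported
  in that basis.
* LMS: unit-power reference, $\mu = 5\times10^{-5}$, 8 taps, zero
  initial weights, ≤ 500 sweeps, relative stopping tolerance $10^{-6}$;
  stability warning when $\mu \cdot \text{taps} \cdot P_{ref} \ge 1$.
* Spectra: $M$ a power of two $\ge L$; grid $k f_s/M$, $k = 0..M/2$;
  ties in peak picking resolve to the lower frequency.
* Respiration band starts at 0.05 Hz, not DC, so drift cannot win the
  argmax.
* Error tables round to two decimals only at presentation.

The whole validation suite — including the end-to-end simulation study
at the full $M = 2^{17}$ grid — runs in a few seconds on one CPU, with
5-s, 500-sample records and 12–20-s segmented records as the standard
problem sizes.
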