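# radvital

Non-contact monitoring of respiration rate (RR) and heartbeat rate (HR)
with a single continuous-wave (CW) Doppler radar breaks down as soon as
the subject moves: chest-wall motion is millimetres, while a swaying or
walking torso moves by centimetres at tens of mm/s and buries the vital
signs completely. `radvital` implements a single-radar processing chain
that recovers both rates anyway, for researchers working with quadrature
(I/Q) baseband recordings of CW Doppler sensors.

## The method

The radar encodes total target displacement $x(t)$ in the baseband
phase. With carrier wavelength $\lambda$ and a constant residual phase
$\phi$,

$$B_I(n) = \cos\!\Big[\tfrac{4\pi d_0}{\lambda} + \tfrac{4\pi x(n)}{\lambda} + \phi\Big],
\qquad B_Q(n) = \sin[\,\cdot\,],$$

and the chain proceeds in four stages:

1. **DACM demodulation.** The extended differentiate-and-cross-multiply
   accumulator
   $\varphi(n) = \sum_{m=2}^{n}
   \frac{B_I(m)\Delta B_Q(m) - \Delta B_I(m)\,B_Q(m)}{B_I^2(m)+B_Q^2(m)}$
   recovers the relative phase without explicit unwrapping;
   $\hat x(n) = \varphi(n)\lambda/4\pi$.
2. **Random-body-movement (RBM) cancellation.** A low-order polynomial
   $x_f(n) = \sum_{i=0}^{Y} p_i n^i$ fitted to $\hat x$ approximates the
   body translation and drives an LMS adaptive noise canceller,
   $w(n{+}1) = w(n) + 2\mu\,x_f(n)z(n)$, swept over the record until the
   mean of $z^2$ stops decreasing. The residual
   $z(n) = \hat x(n) - w^T x_f(n)$ is the vital-sign estimate.
3. **Spectral rate estimation.** The cosine-projection (N-DCT) spectrum
   $X[k] = 2\sum_{n=0}^{L-1} z(n)\cos(2\pi k n/M)$ with $M = 2^{17} \gg L$
   localises peaks on a fine grid with a main lobe about half as wide as
   the zero-padded FFT's. RR is the band-limited argmax below 0.6 Hz; HR
   the argmax in 0.8–3 Hz after a zero-phase high-pass
   ($f_{stop} = 0.7$ Hz, $f_{pass} = 0.9$ Hz) removes the respiration
   fundamental.
4. **Direction segmentation.** Back-and-forth motion is cut wherever the
   smoothed displacement derivative changes sign, so each ~3 s part
   satisfies the constant-velocity assumption and is processed alone.

Accuracy is summarised per experiment part by
$\mathrm{error} = (R_{measure}-R_{ref})/R_{ref}\times 100\%$ and the
mean of absolute part errors.

## Worked example

```r
library(radvital)

# synthetic subject: 3 mm respiration @ 0.4 Hz, 1 mm heartbeat @ 1.3 Hz,
# walking away at 30 mm/s; 10 GHz radar sampled at 100 Hz for 5 s
iq <- synth_motion() |> synth_baseband()
iq
#> # A tibble: 500 × 3
#>       t      I     Q
#>   <dbl>  <dbl> <dbl>
#> 1  0    -0.106 0.994
#> 2  0.01 -0.228 0.974
#> 3  0.02 -0.343 0.939
#> # i 497 more rows

fit <- iq |> demodulate() |> cancel_rbm(order = 3)
fit
#> <anc_fit> 8 taps, mu = 5e-05, 36 sweep(s) (converged), final mean z^2 = 4.81 mm^2

est <- extract_vital_signs(demodulate(iq))
est[c("rr", "hr", "rr_prominence", "hr_prominence")]
#>       rr    hr rr_prominence hr_prominence
#> 1 0.3998 1.295         4.345         26.91
```

The estimated rates land on the generating frequencies: RR 0.3998 Hz
(truth 0.4 Hz, −0.05 %) and HR 1.295 Hz (truth 1.3 Hz, −0.4 %), even
though the 150 mm body translation exceeds the heartbeat amplitude by
two orders of magnitude. `autoplot(fit)` shows the cancelled record;
`run_simulation_demo()` repeats the study across fit orders 1–5 and both
spectral estimators, and `run_record_pipeline()` runs the segmented
workflow on a `t,I,Q` CSV. A command-line wrapper with the same stages
lives at `inst/cli/radvital`.

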