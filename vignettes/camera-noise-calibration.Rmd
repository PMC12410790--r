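---
title: "Camera noise calibration and SNR budgeting: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Camera noise calibration and SNR budgeting: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camsnr)
```

## The image-formation model

`camsnr` models a scientific camera pixel as a chain of independent noise
processes. Photons from the scene arrive as a Poisson process with rate
`P` (photons/s/px); a fraction `QE` become photoelectrons, so an exposure
of `t` seconds yields `Poisson(QE·P·t)` signal electrons. Heat adds
`Poisson(Dark·t)` dark-current electrons. If the electron-multiplying
(EM) register is active, charge shifting adds `Poisson(CIC)` spurious
electrons per frame. The summed electrons pass through the EM cascade,
then Gaussian read noise of SD `sigma_read` electrons is added, and the
ADC digitizes: `GV = round(K·electrons + bias)`, clipped to
`[0, 2^bitDepth - 1]`. Because the sources are independent, variances
add:

`sigma_total² = sigma_photon² + sigma_dark² + sigma_CIC² + sigma_read²`

and the theoretical budget (`theoreticalNoiseBudget()`) reproduces this
identity exactly by construction; simulations reproduce it statistically
(the test suite checks agreement within three Monte-Carlo standard
errors on ~1e5-pixel frames).

### The EM-gain cascade and the excess-noise factor

The multiplication register amplifies stochastically. The package offers
three models:

* `sqrt2` (default): given `n` input electrons, the output is drawn from
  `Gamma(shape = n, scale = Gain)`. The conditional mean is exactly
  `Gain·n` and the conditional variance `n·Gain²`, so Poisson(λ) input
  emerges with variance `2·Gain²·λ` — an excess-noise factor of exactly
  `EN = √2`, the standard high-gain limit. This is the classic
  output-distribution model for EM registers and is cheap to sample.
* `branching`: an explicit cascade of `nStages` (default 500) stages, in
  each of which every electron independently duplicates with probability
  `p = Gain^(1/nStages) − 1`. Its excess-noise factor is computed in
  closed form from the Galton-Watson variance recursion and tends to √2
  from below as the gain grows (≈1.404 at gain 103.5). The cascade is the
  physical model; `sqrt2` is its two-moment surrogate. The two agree on
  the mean exactly and on the variance within 2% for gains ≥ 50, which
  the tests verify both analytically and by Monte Carlo.
* `none`: deterministic multiplication (`EN = 1`), which turns the model
  into a plain CCD; at unity gain all three models coincide and CIC is
  not injected (the register is idle).

Only the first two moments of the cascade are identifiable from
mean/variance calibration data, which is why the default is the
two-moment Gamma surrogate and the branching model is kept for
validation. `EN` is exposed as a parameter in every estimator that needs
it (default `√2`; the value 1.4 seen in some data sheets differs by
0.3%, well below the estimators' statistical resolution).

## Parameters, units, defaults

| parameter | unit | default | rationale |
|---|---|---|---|
| `quantumEfficiency` | fraction | 1.0 | `QE` and `P` only ever appear as a product in the estimators, so the split is unidentifiable; with QE = 1 scene flux reads as detected photons |
| `darkCurrent` | e-/s/px | 0 | off unless under study |
| `cic` | e-/px/frame | 0 | off unless under study; injected before the gain register, so its noise is amplified with excess noise, and it contributes nothing at unity gain |
| `readNoise` | e- RMS | 0 | off unless under study |
| `kRatio` (K) | GV/e- | 1 | unit conversion; every reported number is labelled e- or GV |
| `bias` | GV | 100 | typical ADC offset; large enough that a 30 GV-SD dark frame essentially never clips at zero |
| `bitDepth` | bits | 16 | common scientific ADC |
| `sensorShape` | px | 653 × 492 | the frame-transfer CCD format used throughout the examples |
| `nStages` | stages | 500 | typical EM-register length; the excess-noise factor is insensitive to it above a few hundred |

ADC rounding uses round-half-even (R's `round()`), and clipping at the
bit depth logs a warning when more than 1% of pixels saturate (the frame
is still returned, since partial saturation can be informative).

## The suite generator

`generateSuite()` produces the frame suites each estimator needs, with
every other noise source suppressed by design: zero-exposure unity-gain
closed-shutter frames for read noise; a closed-shutter exposure series
(always including 0 s) for dark current; open-shutter uniform-flux
stacks with matched darks for photon-transfer work; light/dark pairs at
unity gain and at each gained setting for EM gain and CIC; and a
synthetic cell scene (non-overlapping disks on a uniform background,
optional uniform stray-light flux) for the SNR metrics.

Two sizing choices matter:

* **Steady-source brightness.** The gain estimator wants a source bright
  enough that the above-dark SD is small relative to the mean, so the
  generator targets ~1000 GV above dark at unity gain. At high gain that
  target would saturate a 16-bit ADC, so `steadySourceFlux()` caps the
  flux such that the mean plus six SDs at the highest gain stays below
  saturation; the six-SD margin accounts for the right skew of the
  EM-amplified intensity distribution. The cap, not the target, binds
  for gains above ~60.
* **Seeds.** Every frame's seed derives deterministically from the
  recipe's master seed (`deriveSeed()`, a fixed affine map modulo
  2³¹−1), so identical recipes are bit-identical, different stacks of
  one suite use disjoint streams, and partial reruns are stable.

The generator emulates photon statistics, camera noise and digitization
faithfully, but *not* pixel-response non-uniformity, hot pixels, frame
shifts, smear, PSF blur, or photobleaching. Real cameras exhibit extra
frame-to-frame variability from these effects, which inflates measured
dark-image SDs and can hide a small dark current at short exposures even
when the ideal Poisson model would reveal it. Passing recovery tests on
simulated frames therefore demonstrates that the estimators are correct
and unbiased under the stated model — not that a physical instrument
will match its data sheet.

## Estimator design choices

* **K at unity gain only.** The photon-transfer ratio
  `sigma_photon(GV)²/S(GV)` equals `K` only without multiplication; with
  gain it would equal `EN²·Gain·K`. `estimateKRatio()` rejects gained
  stacks rather than silently folding the gain in.
* **ROI statistics.** Noise is measured as the population SD of a single
  rectangular ROI per frame (default: centered, 20% of each dimension),
  averaged across frames — matching how background regions are measured
  in practice. A temporal per-pixel variant exists only inside the
  pixel-independence check, which compares consecutive difference images
  against the expected `√(sd_i² + sd_{i+1}²)`.
* **Difference images.** Computed as `(a + bias) − b` with no
  truncation; the explicit bias mirrors integer pipelines where a
  negative difference would clip to zero and corrupt the noise estimate.
* **Dark-current fit.** Isolated dark variance (in e-²) is regressed on
  exposure time through the origin by unweighted least squares, using
  only exposures where the variance exceeds the zero-exposure variance.
  Undetected exposures are flagged, never zero-filled into the fit, and
  a fully undetected series returns the implied upper bound
  `0.25·sigma_read²/max(t)` instead of a value. Variance (not SD) is the
  response because the model is linear in variance.
* **CIC.** `[sigma²(gi) − sigma²(g0) − (EN²G² − 1)·Dark·t] / (EN²G²)`,
  with all variances converted to electrons via `K`. Negative results
  clamp to zero with a `detected = FALSE` flag; per-gain estimates are
  averaged with equal weight when several gains are available. The same
  clamp-and-flag convention applies to every variance subtraction in the
  package (photon-noise isolation, excess background, camera-independent
  SNR), so no estimator ever returns a negative noise, and an
  undetectable quantity is never reported as a hard zero.
* **Gain-normalized excess background.** When a dark frame's variance is
  dominated by amplified CIC, `sigma_DarkImage/(K·Gain) ≈ EN·√CIC`
  electrons, so the relative excess `r = sigma_EBG/sigma_DarkImage`
  converts to photoelectrons as `r·EN·√CIC`. The report records which
  normalization was applied.

## Problem sizes and tolerances

The recovery tests and the acceptance script use full-format frames
(653 × 492 px): 5 zero-exposure frames for read noise, 10 light/dark
pairs for K, 3 frames per exposure over 120–600 s for dark current, and
3 frames per condition for the gain series at gains 2.40, 9.03 and
103.5. At these sizes the estimators' statistical error is roughly
0.3–1% for read noise, K and EM gain and 1–3% for dark current and CIC,
comfortably inside the 3%/10% tolerances asserted. The randomized
end-to-end property test uses 326 × 246 px sensors and a wider ADC
offset (2000 GV) so that the largest read-noise × K draws do not clip at
zero; it conditions the dark-current assertion on the series actually
reaching past the negligibility bound `0.25·sigma_read²/Dark`, and the
CIC assertion on the amplified CIC dominating the read-noise variance —
outside those regimes the quantities are statistically undetectable by
design, and only the flag semantics are checked.

## Known limitations

* No per-pixel gain/offset maps, hot-pixel masking, or flat-fielding;
  the pixel-independence check is diagnostic, not corrective.
* The excess-noise factor is configurable but not itself fitted.
* Dark current accumulated during readout/frame transfer is ignored:
  `t` is the commanded exposure, and a 0-s closed-shutter frame is
  treated as pure read noise.
* Cell scenes are geometric stand-ins (disks, no PSF, no morphology);
  they exercise the SNR metrics' contrast statistics, nothing more.
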