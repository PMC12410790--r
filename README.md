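# camsnr

Camera noise calibration and signal-to-noise budgeting for quantitative
fluorescence microscopy.

Single-cell fluorescence measurements live or die by the signal-to-noise
ratio (SNR) of the raw images, and the SNR is bounded by the camera:
EMCCD and sCMOS sensors ship with marketed read noise, dark current and
(for EMCCDs) clock-induced charge, but those numbers are often wrong on
real instruments — sometimes by several fold — and every excess electron
of background noise costs sensitivity exactly where low-light imaging
needs it most. `camsnr` lets microscopists verify their camera and budget
their noise without any vendor tooling: it simulates the full
image-formation noise chain, recovers every camera parameter from simple
dark-frame and photon-transfer experiments, and quantifies how much of an
image's background noise comes from the camera versus from stray light in
the microscope.

## The model

The total noise of a pixel (in electrons, before digitization) is the
quadrature sum of four independent sources:

    sigma_total^2 = sigma_photon^2 + sigma_dark^2 + sigma_CIC^2 + sigma_read^2

with, for an EM gain `G`, quantum efficiency `QE`, photon flux `P`,
exposure `t`, dark current `Dark`, clock-induced charge `CIC`, and
excess-noise factor `EN ≈ √2` introduced by the stochastic
electron-multiplication cascade:

| source              | mean (e-)        | SD (e-)                  |
|---------------------|------------------|--------------------------|
| photon shot         | `G·QE·P·t`       | `EN·G·√(QE·P·t)`         |
| dark current        | `G·Dark·t`       | `EN·G·√(Dark·t)`         |
| clock-induced charge| `G·CIC`          | `EN·G·√CIC`              |
| readout             | bias offset      | `sigma_read`             |

The ADC converts electrons to gray values (GV) with a conversion ratio
`K` (GV per electron) and a constant bias. The SNR of a signal producing
`N_e = QE·P·t` photoelectrons is `N_e / sigma_total`.

Each calibration estimator isolates one parameter by suppressing all the
others:

* **read noise** — SD of 0-gain, 0-s closed-shutter frames, divided by `K`;
* **K** — photon-transfer mean-variance ratio,
  `K = sigma_photon(GV)^2 / S(GV)`, at unity gain;
* **dark current** — slope of isolated dark variance against exposure over
  a closed-shutter exposure series, with a detection rule (exposures where
  the variance does not exceed the zero-exposure variance are flagged, not
  zero-filled);
* **EM gain** — intensity ratio of a steady light source imaged with and
  without gain, both background-subtracted;
* **CIC** — excess variance of a gained short-exposure dark frame over the
  ungained one, divided by `EN²·G²`.

On top of these the package computes SNR diagnostics for real images:
excess background noise relative to a matched dark frame
(`sigma_BG² = sigma_DarkImage² + sigma_EBG²`), the gain-normalized noise
floor `EN·√CIC` in photoelectrons, the fraction of background variance
contributed by stray light (`r²/(1+r²)` for relative excess `r`), and the
camera-independent SNR of cell regions (background-subtracted cell
intensity over the photon shot noise of the background).

## Worked example

Simulate a full calibration campaign for a noisy EMCCD (read noise
25.3 e-, K = 1.20 GV/e-, dark current 2.5 e-/s/px, CIC 25 e-) and recover
its parameters:

```r
library(camsnr)

spec <- demoCameraSpec()
budget <- theoreticalNoiseBudget(spec,
            AcquisitionSettings(0.05, 103.5, "g3", shutterOpen = FALSE))
budget
#> NoiseBudget (SD per source)
#>             electrons gray_values
#> mean_signal    0.0000      0.0000
#> sd_photon      0.0000      0.0000
#> sd_dark       51.7500     62.1000
#> sd_cic       731.8555    878.2266
#> sd_read       25.3000     30.3600
#> sd_total     734.1190    880.9428

res <- runPipeline(demoRunConfig(masterSeed = 42))
res$calibration
#> CalibrationReport
#>   read noise   : 25.8 e- (SD over frames 0.35)
#>   K            : 1.177 GV/e-
#>   dark current : 2.52 e-/s/px
#>   EM gain      : g1=2.4, g2=9.014, g3=103.5
#>   CIC          : 26 e- (average over gains)
#>   pixel independence: 99.5% similarity
```

The noise budget shows what dominates a gained dark frame: amplified
clock-induced charge (878 GV) dwarfs both the amplified dark current
(62 GV at 50 ms) and the read noise (30 GV), which is why CIC sets the
sensitivity floor of an EM camera. The pipeline then recovers all five
parameters from simulated frames within a few percent of the ground
truth, and reports the excess background noise of a synthetic cell scene
relative to its matched dark frame:

```r
res$background
#> BackgroundReport
#>   background   : mean 339.2 GV, SD 35.02 GV
#>   matched dark : mean 100.2 GV, SD 29.85 GV
#>   excess noise : 18.31 GV (0.613 x dark)
#>   gain-normalized excess: 4.42 e-
```

A command-line surface is available as `exec/camsnr` with `simulate`,
`calibrate`, `snr-report` and `demo` subcommands; frames travel as 16-bit
multi-page TIFF with JSON sidecars, camera specs as YAML/JSON.

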