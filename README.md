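# slicemetrics

Quantitative analysis of network states and oxygen metabolism in
hippocampal slice recordings.

Hippocampal slices in an interface chamber express the major network
rhythms of the intact hippocampus: persistent **gamma oscillations**
(30–70 Hz, typically around 40 Hz, induced cholinergically in CA3),
**theta-nested gamma** under sinusoidal optogenetic drive, and
**sharp wave-ripples** (SPW-R) — intermittent large deflections at
per-minute rates carrying fast >180 Hz "ripple" oscillations. Changes in
the energy substrate (glucose vs. lactate) alter these rhythms and can
evoke recurrent high-amplitude **bursts**, and they shift the tissue's
oxygen consumption. `slicemetrics` is for electrophysiologists who want a
reproducible, scripted version of the standard desk analysis of such
recordings:

- **Spectral descriptors** — Morlet wavelet spectrograms, Welch power
  spectral density, and the scalar peak metrics *f* (peak frequency),
  *Power* (PSD at the peak), *AuC* (PSD integral between the half-maximum
  crossings) and *FWHM* (width between those crossings); normalized
  band-power time courses in 1-min segments.
- **Temporal coherence** — the time constant *TAU* of the decaying
  exponential `A·exp(−lag/TAU)` fitted to the peaks of the band-limited
  autocorrelation.
- **Event detection** — envelope-threshold burst detection against a
  pre-switch baseline (incidence, amplitude, intervals, onset in minutes),
  and dual-threshold SPW-R detection (incidence/min, amplitude, half-peak
  duration, ripples per event in the 180–300 Hz band).
- **Cross-region propagation** — normalized cross-correlation of the
  band-limited signals of two channels (CA3 → CA1): *Similarity* (its
  maximum) and *lag* at that maximum.
- **Oxygen metabolism** — a steady-state one-dimensional
  diffusion–consumption model of an interface-chamber slice
  (`D·C″ = Vmax·C/(Km+C)` in the tissue, a convective boundary layer on the
  gas-facing side, fixed concentration at the solution side), solved by
  damped Newton on second-order finite differences, and inverted by
  nonlinear least squares to estimate **CMRO₂** (= `Vmax`) and the lowest
  tissue O₂ from microsensor depth profiles.
- **Synthetic data** — a seeded generator producing
  ground-truth-annotated recordings of each state (1/f background,
  frequency-jittered gamma, theta-modulated envelopes, Poisson SPW-R and
  burst events) and noisy forward-model oxygen profiles, so every detector
  and estimator can be validated against known truth.

Because the underlying laboratory recordings are not publicly deposited,
the synthetic generator is a first-class module: all validation, tests and
the acceptance script run on data it produces.

## Worked example

```r
library(slicemetrics)

## -- gamma oscillation metrics on a synthetic 2-min recording --------------
g <- gen_recording(synth_spec("gam", duration = 120, seed = 1))
g$recording
#> LFP recording: 1 channel(s) [ca3_uV], 120 s at 5000 Hz (600000 samples)

summarize_spectrum(compute_psd(g$recording), band = "gamma")
#> Spectral peak in 30-70 Hz: f = 39.5 Hz, Power = 511.5 a.u., FWHM = 2.149 Hz, AuC = 950.8

autocorr_tau(g$recording, band = "gamma", max_lag = 1)
#> Autocorrelation: TAU = 0.1438 s (A = 1.55, R² = 0.937, 13 peaks)
```

The PSD peaks at 39.5 Hz — the generator's 40 Hz carrier within one 0.5 Hz
Welch bin — with a narrow FWHM (~2 Hz): a frequency-stable gamma rhythm.
The autocorrelation decays with TAU ≈ 0.14 s, i.e. the oscillation stays
phase-coherent for roughly six gamma cycles, set by the generator's
default 1 Hz frequency jitter.

```r
## -- CMRO2 from a bundled synthetic oxygen depth profile -------------------
prof <- read_oxygen_csv(system.file("extdata", "synthetic_oxygen_profile.csv",
                                    package = "slicemetrics"))
fit <- fit_cmro2(prof, oxygen_model())   # 400 µm slice, concentrations in units of C_top_far
fit
#> CMRO2 fit (steady-state diffusion-consumption model)
#>   CMRO2 (Vmax): 0.0574369 concentration/s
#>   residual RMS: 0.01851;  lowest O2 of fit: 0.003506;  converged: TRUE

cmro2_contrast(fit, 0.04)   # e.g. against a fitted quiet-state rate of 0.04/s
#> fold 1.436, percent 43.6
```

The bundled profile (labelled synthetic; generated with `Vmax = 0.06` and
2% measurement noise) is recovered at 0.0574 /s — within 5% of truth —
and the fitted curve bottoms out near zero O₂ mid-slice, the anoxic-core
regime the saturable kinetics keep well-posed. `cmro2_contrast()` reports
state comparisons as fold / percent change. The fitted object supports
`coef()`, `predict()`, `residuals()`, `simulate()` and `plot()`.

A configured end-to-end run (`run_pipeline(run_config(mode = "spwr", ...))`)
produces a flat JSON report of all metrics with provenance (config hash,
version, seed); `inst/cli/slicemetrics.R` exposes the same workflow as
`synth` / `analyze` / `oxygen-fit` / `report` shell subcommands.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch
on seeded synthetic data — gamma spectral metrics and cross-region lag,
SPW-R and burst detection, and the CMRO₂ inversion — and writes its
results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Progress and the headline numbers of each stage are printed to stderr.
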