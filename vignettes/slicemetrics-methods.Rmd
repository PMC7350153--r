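---
title: "Methods: network-state metrics and slice oxygen modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-state metrics and slice oxygen modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slicemetrics)
```

This vignette is the package's own account of its methods: what is being
modelled, which knobs matter, what the synthetic generator does and does not
emulate, and where genuinely open design choices were settled.

## 1. Scope and assumptions

`slicemetrics` quantifies extracellular LFP recordings from hippocampal
slices across three network states — persistent gamma (30–70 Hz),
theta-nested gamma, and sharp wave-ripples — together with substrate-driven
bursting, CA3→CA1 propagation, and tissue oxygen metabolism in an interface
chamber. Throughout, the signal is treated as a uniformly sampled,
single- or dual-channel voltage trace in µV; no spike-level or biophysical
network structure is assumed. Hypothesis testing across experimental groups
is out of scope: group results are summarized descriptively as
median ± IQR (75th − 25th percentile) with min–max range via
`summarize_group()`, and any inferential statistics are left to standard
tools.

## 2. Spectral descriptors

**PSD.** `compute_psd()` uses Welch's method with 2-s Hann windows and 50%
overlap. The 0.5 Hz resolution is deliberate: the FWHM of a frequency-stable
~40 Hz gamma peak is of order 1–3 Hz, so the estimator must resolve
substantially below that. The periodic Hann window with the `1/(fs·Σw²)`
density normalization makes the PSD variance-conserving (Parseval), which
the tests verify against the sample variance of white noise.

**Peak metrics.** `summarize_spectrum()` defines, within an analysis band
(gamma fixed at 30–70 Hz, theta at 3–8 Hz):

- *f*: argmax of the PSD in the band (ties broken toward the lowest
  frequency);
- *Power*: the PSD at *f*;
- *FWHM*: distance between the two half-maximum crossings, located by
  linear interpolation walking outward from the peak (over the full
  spectrum, so a wide peak is not clipped at the band edge);
- *AuC*: the trapezoidal integral of the PSD between those two crossings.

Tying AuC to the same crossings as FWHM makes the two metrics describe one
spectral region and keeps both reproducible; the shaded-area convention
this numerically pins down is otherwise a matter of plotting. If the
in-band maximum sits on a band edge with no interior local maximum, the
summary is returned `flagged` rather than silently reported.

**Wavelet spectrogram.** `wavelet_spectrogram()` uses analytic Morlet
wavelets with 6 cycles on a linear grid (default 1 Hz step), implemented as
multiplication with a Gaussian of width `f0/6` on the positive-frequency
axis. Six cycles is the standard compromise between time and frequency
resolution at gamma frequencies. Power is block-averaged to a configurable
output step (default 10 ms); block means preserve windowed band power
exactly, which is what `normalized_power_timecourse()` consumes (default
1-min non-overlapping segments, normalized to the first segment).

**Autocorrelation TAU.** `autocorr_tau()` band-pass filters, computes the
normalized autocorrelation by FFT, finds its positive-lag local maxima, and
fits `A·exp(−lag/TAU)` by unweighted least squares on the log peak values.
Two numerical guards matter:

- non-positive peaks cannot enter the log fit and are excluded (positivity
  clamp);
- the fit is restricted to the leading decade of the decay (peaks ≥ 10% of
  `r(0)`). Late, near-floor peaks are dominated by sample-autocorrelation
  noise, and the concavity of the logarithm turns that noise into a
  systematic flattening of the fitted slope. Validated against an AR(2)
  process with known pole radius (`TAU = −Δt/ln r`), the restriction
  roughly halves the worst-case error.

If the fitted TAU exceeds the analysis lag range (an undamped sinusoid is
the limiting case) the result is flagged `non_decaying` instead of
reporting a meaningless extrapolated constant.

**Filtering.** No IIR filter-design package is assumed. All band-limiting
applies the *squared* magnitude response of an order-4 Butterworth design
in the frequency domain, which is mathematically the magnitude response of
forward–backward (zero-phase) filtering — exactly zero phase, hence safe
for the lag estimates — with ~1 s mirror padding against edge transients.

## 3. Event detection

**Bursts** (`detect_bursts()`). The envelope is `|x|` low-passed at 20 Hz.
The threshold is `mean + k_sd·SD` (default `k_sd = 5`) of the *pre-switch
baseline* envelope, with two passes of suprathreshold exclusion so that
occasional baseline transients do not inflate the SD. A high multiplier is
required because bursts ride on ongoing gamma: the threshold must clear the
gamma envelope, not a flat noise floor. Events are merged within a 500 ms
refractory period; amplitude is the peak absolute deflection, incidence is
counted over the post-switch period, and onset is reported in minutes after
the switch, the convention in which burst latencies are given. At least
60 s of baseline is required.

**Sharp wave-ripples** (`detect_spwr()`). Candidates are excursions of the
2–45 Hz filtered trace beyond `k_sd = 3` SD (SD from two-pass event
exclusion); an event is *confirmed* only if its peak exceeds
`k_sd_peak = 5` SD. The dual threshold is essential, not cosmetic: by
Rice's formula a Gaussian 2–45 Hz band crosses 3 SD roughly 16 times per
minute, so a single 3-SD rule cannot meet a <1/min false-positive budget,
while 5 SD excursions of pure noise are expected well under once per hour.
Detection is restricted to the dominant deflection polarity (configurable;
auto-detected as the sign of the larger extreme): zero-phase high-pass
filtering of a monophasic sharp wave creates opposite-sign rebound lobes
that would otherwise be counted as separate events. Event boundaries are
the half-peak crossings of the filtered trace (duration in ms); events with
gaps under 20 ms are merged. Ripples are counted as local maxima of the
180–300 Hz trace exceeding `ripple_k_sd = 2` × its event-free SD within the
event window, gated on the event actually containing a fast packet (ripple-
band peak ≥ 2·`ripple_k_sd`·SD) — without the gate, events whose fast
component lies below 180 Hz would still accumulate one or two noise peaks.
The 180 Hz lower edge encodes the definition of a ripple as a >180 Hz
oscillation; 300 Hz is a conventional upper edge within sampling limits.

**Cross-region similarity and lag** (`similarity_and_lag()`). Both channels
are gamma-band filtered; the normalized cross-correlation is evaluated for
lags within ±25 ms (one gamma cycle — a wider window would admit
cycle-skipped maxima for a periodic signal). *Similarity* is the maximum,
*lag* its argument (positive = channel 1 leads), ties resolved toward the
smallest |lag|. Whether the original "similarity" statistic was a
cross-correlation maximum or a coherence is not decidable from the
available description; the cross-correlation maximum was chosen because it
yields the propagation lag from the same computation and is bounded in
[−1, 1].

## 4. The slice oxygen model and CMRO₂ inversion

**Forward model.** Steady-state, one-dimensional, two layers:

- fluid boundary layer `[−δ, 0]`: pure diffusion (`D_fluid`), far-field
  concentration `C_top_far` fixed at `−δ`. At the tissue surface this
  reduces to the Robin condition
  `D_tissue·C′(0) = (D_fluid/δ)·(C(0) − C_top_far)`; `δ = 0` degenerates to
  a Dirichlet surface. The single parameter δ (default 100 µm) is the
  model's representation of convective transport above the slice.
- tissue `[0, L]`: `D_tissue·C″ = Vmax·C/(Km + C)`, with fixed `C_bottom`
  at depth `L`. `Vmax` *is* the CMRO₂.

Michaelis–Menten kinetics with a small `Km` (default 1% of `C_top_far`)
approximate zero-order consumption at physiological O₂ while keeping an
anoxic core well-posed: as `C → 0` consumption shuts off smoothly, so no
explicit free-boundary treatment is needed and the maximum principle
(`0 ≤ C ≤ max(C_top_far, C_bottom)`) holds for all parameters.

Defaults: `L = 400 µm` (acute slice; ~250 µm for cultures),
`D_tissue = 1.5e3 µm²/s`, `D_fluid = 2.0e3 µm²/s`, concentrations in
arbitrary units normalized to `C_top_far = 1` (calibrated µM may be
substituted throughout), and `C_bottom = 0.5·C_top_far` for the
interface-chamber asymmetry — supply through the membrane/solution side is
weaker than from the humidified gas above. All transport constants are
configurable because the original model's exact constants and units are not
available; none of the package's conclusions depend on their absolute
scale, only the fitted `Vmax` does, in the same units as the profile.

**Numerics.** Second-order central differences on a uniform grid (default
401 points), with a second-order one-sided stencil for the Robin boundary;
the Jacobian is tridiagonal plus one extra entry, eliminated analytically
before a Thomas solve. Damped Newton iteration (step halving on residual
increase, positivity clamp, update tolerance `1e-12` relative) converges in
a handful of iterations from a linear initial profile; halving the grid
spacing changes the solution by under 0.01%, and the zero-order limit
(`Km → 0`, symmetric Dirichlet supply) reproduces the parabolic closed form
`C0 − Vmax/(2D)·z·(L−z)` to better than 0.1%.

**Inversion.** `fit_cmro2()` minimizes the sum of squared differences
between the forward solution (spline-interpolated to the measured depths)
and the profile, with `Vmax` free and optionally `C_bottom`. Three starts
(0.3×, 1×, 3× of a curvature-based guess `8·D·ΔC/L²`) are run through
box-constrained quasi-Newton and the best residual wins; convergence
diagnostics, per-start residuals and the residual RMS are retained in the
returned model object, which supports the standard fitted-model verbs
(`coef`, `predict`, `residuals`, `simulate`, `plot`). On noiseless
synthetic profiles the recovery is exact to <1e-4 relative; with 2%
measurement noise the estimator is unbiased to within a few percent, and
fixing `Km` at a value wrong by ±50% shifts the recovered `Vmax` by well
under 15% — the CMRO₂ estimate is driven by profile curvature, not by the
kinetic constant. `cmro2_contrast()` expresses two fits as fold and percent
change, the form in which state contrasts are reported.

## 5. What the synthetic generator emulates — and what it does not

`gen_recording()` produces, deterministically per seed:

- **1/f background**: spectrally shaped Gaussian noise (default exponent 1,
  SD 10 µV) — the canonical LFP background.
- **Gamma**: a sinusoid (default 40 Hz, 50 µV peak) whose instantaneous
  frequency carries mean-reverting Ornstein–Uhlenbeck jitter (default SD
  1 Hz, correlation time 1 s) and whose amplitude fluctuates slowly
  (CV 0.25). An OU process was chosen over a pure random-walk frequency so
  that long recordings remain spectrally stationary; its SD is the single
  knob that jointly broadens FWHM and shortens TAU, mirroring how less
  synchronized preparations show wider peaks and faster decorrelation.
- **Theta-gamma**: the gamma envelope multiplied by
  `(1 − d) + d·(1 + cos θ)/2` at the theta phase θ (default 5 Hz, depth
  `d = 1`), plus a theta-frequency component, emulating sinusoidal
  optogenetic drive.
- **SPW-R**: Poisson events (default 12/min) thinned to a minimum
  separation of twice the sharp-wave width so ground truth stays
  unambiguous for F1 scoring; each event is a Gaussian monophasic
  deflection (FWHM 50 ms, 150 µV, 10% amplitude jitter) carrying a
  Hann-windowed ripple packet (default 5 cycles at 200 Hz, 40% of the SPW
  amplitude) centered on the peak.
- **Bursts**: after the condition-switch time, Poisson events (default
  0.3/s nominal, 500 ms minimum separation) with a stereotyped biphasic
  waveform — 5 ms rise, 30 ms decay, delayed 40% rebound — at 400 µV,
  large against gamma but not modelled as epileptiform afterdischarges.
- **Two channels**: channel 2 is the delayed signal (default 5 ms CA3→CA1
  lag) plus noise that shares a configurable fraction with channel 1.

`gen_oxygen_profile()` evaluates the forward model on a depth grid and adds
i.i.d. Gaussian noise (clamped at zero, as a sensor reports no negative
concentration).

The generator deliberately does **not** emulate: spike contamination or
unit activity, non-stationary drift, electrode artifacts, epileptiform
discharge morphology, pharmacological dynamics, state transitions within a
recording (other than the burst switch), or correlated/heteroscedastic
sensor noise in oxygen profiles. A green test therefore establishes that
the estimators are correct and well-calibrated *in this stated world* —
unbiased incidence, F1 ≥ 0.95 at realistic SNR, sub-sample lag recovery,
<5% CMRO₂ bias at 2% noise — not that the fixed default thresholds are
optimal for any particular rig's recordings. Threshold parameters are
exposed precisely because real data will need them tuned.

## 6. Degenerate inputs and tie-breaking, collected

- Zero-amplitude generator specs produce exactly zero recordings; zero
  signals yield zero spectra and no events rather than errors.
- PSD ties at equal maxima resolve to the lowest frequency; cross-
  correlation ties to the smallest |lag|.
- `summarize_spectrum()` flags edge maxima; `autocorr_tau()` flags
  non-decaying fits and errors on fewer than three peaks;
  `fit_cmro2()` flags non-convergence rather than returning a number.
- CSV readers reject non-uniform time axes (1 ppm tolerance), naming the
  first offending row; the oxygen reader requires the `depth_um, o2`
  header.
- Reports contain no timestamps, so identical config + seed reproduce
  byte-identical files; the config hash excludes output location and
  verbosity.

## 7. Known limitations

- Oscillation metrics are figure-level descriptors; no phase–amplitude
  coupling, coherence or multitaper estimation is provided.
- The oxygen model is one-dimensional and steady-state: transient O₂
  responses to state switches are summarized only by their plateau
  profiles, and lateral diffusion near the sensor is ignored.
- Concentration units are relative unless the user supplies calibrated
  profiles; fitted CMRO₂ inherits the profile's units.
- Detector defaults were set against the synthetic stated world and
  standard practice, not against the original recordings, which are not
  publicly available.
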