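Package: slicemetrics
Title: Network-State Metrics and Oxygen Metabolism Modelling for
    Hippocampal Slice Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of extracellular local field potential
    recordings from hippocampal slice preparations across network states
    (persistent gamma oscillations, theta-nested gamma, sharp wave-ripples):
    Morlet wavelet spectrograms, Welch power spectra with peak frequency,
    peak power, area under the curve and full width at half maximum,
    autocorrelation decay time constants, burst and sharp wave-ripple event
    detection, and cross-regional similarity and propagation lag. Includes a
    steady-state one-dimensional diffusion-consumption model of tissue
    oxygen in slices (convective boundary layer, Michaelis-Menten
    consumption) with inverse estimation of the cerebral metabolic rate of
    oxygen (CMRO2) from microsensor depth profiles, and a seeded synthetic
    data generator producing ground-truth-annotated recordings and oxygen
    profiles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
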