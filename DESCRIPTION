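Package: itdsim
Title: Binaural Excitatory-Inhibitory Neuron Simulation for Electric and
    Acoustic Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a single excitatory-inhibitory (LSO-type)
    coincidence-counting binaural model neuron driven either by a stochastic
    model of the electrically stimulated auditory nerve (cochlear-implant
    biphasic pulse trains) or by a simplified acoustic auditory periphery
    (amplitude-modulated high-frequency stimuli). Synthesizes the standard
    cochlear-implant-simulating acoustic stimulus classes (SAM tones,
    transposed tones, Gaussian-envelope tone trains, bandpass-filtered click
    trains) and electric pulse trains, and provides spike-train analyses:
    peristimulus-time and period histograms, vector strength, rate-ITD/IPD
    tuning curves, square-root rate contrast, and tuning-curve similarity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
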