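Package: oddballerp
Title: Simulation, Decoding and Recurrent-Network Modelling of Auditory
    Oddball Evoked Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying auditory novelty responses in epidural
    evoked potentials recorded during frequency and intensity oddball
    paradigms. Provides a synthetic cohort generator for epoched
    evoked-potential trials with controlled component structure, the
    standard preprocessing chain (band-pass filtering, baseline
    correction, resampling, standard-trial balancing), time-wise and
    temporal-generalisation decoding with linear support vector machines,
    group-level cluster-based permutation statistics, a hierarchical
    recurrent network that maps short-time Fourier transform cochleagrams
    of pure-tone stimuli onto evoked-response waveforms, hidden-unit
    taxonomy and sample-entropy characterisation of the trained network,
    and simulated probe experiments on tone duration, frequency and
    intensity.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    signal,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
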