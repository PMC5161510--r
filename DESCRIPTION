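Package: vocsketch
Title: Auditory Sketches, Acoustic Distances, and Yes/No Signal Detection
    for Sound Identification Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how simplified renderings of everyday sounds
    are identified by listeners. Implements scalable "auditory sketch"
    synthesis from a cochlear-model spectrogram (constant-Q filterbank
    analysis, sparse maximum-picking, iterative inversion) combined with
    linear-predictive (LPC) modelling of noise components; tonal/noise
    decomposition by sinusoidal partial tracking; two acoustic distance
    models (a dynamic-time-warping distance between auditory spectrograms
    and a Euclidean distance over 13 standardized summary features);
    yes/no signal-detection analysis (d-prime, ln beta, unbiased percent
    correct) with the log-linear correction for perfect discrimination;
    and a synthetic-data generator producing referent-like sounds in four
    morphological profiles, imitation-like degradations, and simulated
    observers for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
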