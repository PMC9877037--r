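Package: thetacode
Title: Dissociating Hippocampal Spatiotemporal Codes from Theta Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for calcium-imaging and local field potential
    (LFP) recordings from mouse hippocampus: binarization of calcium traces,
    information-theoretic classification of place, time and distance cells
    with circular-permutation null distributions, naive Bayes decoding of
    behavioral variables with temporal filtering and bootstrapped error
    z-scores, detection of optogenetic stimulation-modulated cells, and LFP
    analyses (Morlet and moving-window Fourier spectrograms, oscillation
    strength, band-power portions, theta-frequency versus running-speed
    coupling, quiet-rest segmentation and sharp-wave-ripple detection).
    Includes a synthetic-data generator with known ground truth (linear-track
    and open-field behavior, Bernoulli-tuned neurons with calcium-kernel
    convolution, and LFP with speed-coupled theta, stimulation epochs and
    injected ripples) so every stage of the pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
Config/testthat/edition: 3
RoxygenNote: 7.3.3
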