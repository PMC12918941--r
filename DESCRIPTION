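Package: critband
Title: Critical-Band Masking Analysis of Multivoxel fMRI Responses
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for critical-band masking experiments adapted to fMRI
    pattern analysis. Generates octave-band Gaussian noise stimuli via a
    Laplacian pyramid decomposition, enumerates the stimulus design and
    builds trial tables, simulates trial-wise voxel responses and
    behavioral outcomes under the generative structure the analysis
    assumes, computes noise-response and decoding-accuracy matrices from
    trial-wise beta weights, and fits two spatial-frequency channel
    models: a Naka-Rushton by log-Gaussian model of the response to noise
    alone, and a divisive-normalization psychometric model of the effect
    of noise on image decoding. Derived metrics include channel bandwidth
    (FWHM), recognition bandwidth (FW2M of the noise-power threshold
    curve), noise threshold, and noise tolerance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0)
biocViews: Software, StatisticalMethod, Visualization
Config/testthat/edition: 3
RoxygenNote: 7.3.3
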