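Package: spectrolaminar
Title: Spectrolaminar Analysis of Laminar LFP Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for identifying cortical layers from laminar-probe local
    field potential (LFP) recordings. Computes multitaper power spectra and
    relative power maps across probe depth, runs the frequency-based layer
    identification procedure (FLIP) and its frequency-variable variant
    (vFLIP) to locate the alpha-beta peak, gamma peak and alpha-beta/gamma
    crossover channels, estimates current source density (CSD) with z-score
    normalization and early-sink detection, compares relative power maps
    with a structural image-similarity index, and generates synthetic
    trial-structured laminar LFP with a planted spectrolaminar motif for
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'config.R'
    'csd.R'
    'spectral.R'
    'flip.R'
    'flip-run.R'
    'io.R'
    'multitaper.R'
    'pipeline.R'
    'similarity.R'
    'spectrolaminar-package.R'
    'synthetic.R'
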