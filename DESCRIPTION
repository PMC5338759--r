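Package: prpkit
Title: Phoneme-Related Potentials from Continuous-Speech EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the dynamic encoding of acoustic-phonetic and
    speaker information in EEG responses to continuous speech. Computes
    phoneme-related potentials (PRPs) by epoching continuous EEG at
    forced-aligned phoneme onsets, models the stimulus with a peripheral
    auditory spectrogram (cochlear filterbank, hair-cell transduction,
    lateral inhibition), and quantifies time-resolved representational
    structure via pairwise phoneme distance matrices, neural-acoustic
    covariance maps with bootstrap significance, F-statistic time courses,
    UPGMA clustering, non-metric MDS, a regularized least-squares manner
    classifier, and speaker-encoding indices. Includes a synthetic-data
    module that generates phoneme-aligned audio and forward-modelled EEG
    with known ground truth so every analysis stage is testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    signal,
    MASS,
    ape,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
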