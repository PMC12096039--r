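Package: dyadtrf
Title: Multivariate Temporal Response Functions for Dyadic Dance EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Encoding-model analysis of EEG recorded from pairs of freely
    dancing participants. Implements multivariate temporal response
    functions (mTRFs) estimated by lagged ridge regression with
    leave-one-trial cross-validation, generic (leave-one-participant-out)
    prediction, and full-versus-reduced model variance partitioning that
    attributes unique EEG variance (delta r) to music acoustics,
    self-generated movement, partner-generated movement, social
    coordination, and ocular/muscular artifact channels. Also provides
    event-related potential extraction with cluster-based permutation
    statistics, EEG cleaning steps (bandpass, bad-channel flagging, common
    average reference, spatial interpolation), kinematic feature
    extraction (spectral flux, velocity magnitude, coordination sign
    product, principal movements), and a synthetic dyad simulator with
    known ground-truth response kernels so the whole pipeline is testable
    end to end without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
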