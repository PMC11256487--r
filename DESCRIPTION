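Package: remoteEEG
Title: Simulation, Session Control and Validation Analyses for
    Consumer-Grade Wearable EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A hardware-free toolkit for remote electroencephalography
    (EEG) studies built around four-electrode consumer wearables. Provides
    a virtual device simulator (1/f background noise, state-dependent
    alpha rhythm, stimulus-locked N200/P300 deflections), a
    marker-synchronized session engine with an electrode signal-quality
    gate, a zipped timestamped-CSV recording format, and the validation
    analyses used for such platforms: resting-state relative band power
    and alpha blocking, per-channel band-change tables, cluster-based
    permutation t-tests on event-related potentials, and single-epoch
    oddball classification with a minimum-distance-to-means classifier in
    the Riemannian geometry of covariance matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    yaml,
    jsonlite,
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
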