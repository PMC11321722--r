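Package: emgsynergy
Title: Muscle Synergy Analysis of Locomotor EMG with Partitioned NMF
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extraction and comparison of muscle synergies from multichannel
    surface electromyograms recorded during locomotion. Provides EMG envelope
    preprocessing (FIR filtering, rectification, 20-ms integration, spline
    de-spiking, unit-variance normalization), nonnegative matrix factorization
    with multiplicative updates and an 80-percent-R2 dimensionality rule, a
    partitioned NMF that concurrently freezes, updates and appends synergy
    columns, cross-cohort synergy fitting against control-to-control baselines
    with a statistical search for the numbers of updated and additional
    synergies, k-means clustering of synergy vectors with silhouette-based
    cluster counts, segment-span characterization, a motoneuron-loss proxy
    from residual EMG amplitude, and the accompanying clinical statistics
    (normality-gated two-sample tests, sigmoidal motor-score models). A
    synthetic cohort generator with planted pathology supports end-to-end
    validation of every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    minpack.lm,
    nortest,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
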