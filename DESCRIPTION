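Package: grfclust
Title: Gait Pattern Classification from Ground Reaction Force Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sensor-free gait classification for clinical movement analysis.
    Quantifies how closely a patient's three-axis ground reaction force
    (medial-lateral, anterior-posterior, vertical) during one stance phase
    matches a healthy reference: trend similarity via the Pearson
    correlation coefficient and scale similarity via the SMAPE score
    (1 - symmetric mean absolute percentage error). The resulting
    six-dimensional feature vectors are clustered with a Gaussian mixture
    model fitted by an in-package EM algorithm with BIC model selection,
    a k-means/elbow/silhouette cross-check, and per-subject trial
    consistency validation. Includes stance-phase extraction and time
    normalization from raw force-plate recordings, a synthetic gait
    waveform simulator with healthy, magnitude-attenuated and
    shape-distorted patient archetypes, a bundled 16-patient hip
    osteoarthritis feature table, and an end-to-end pipeline with
    group-level curve ensemble statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
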