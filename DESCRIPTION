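Package: qfnirs
Title: Parameterized Quantum Circuit Classifiers for fNIRS Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statevector simulation of parameterized quantum circuits (PQCs)
    and two PQC classifier architectures for binary fear detection in
    functional near-infrared spectroscopy (fNIRS) oxyhemoglobin signals: an
    amplitude-embedding 8-qubit circuit with quantum pooling (AEPQC) and a
    quantum convolutional network (QCNN) with light (K1) and pooling (K2)
    4-qubit kernels plus a 6-qubit classification head. Includes robust
    median/IQR-arctangent preprocessing, Pearson-correlation channel pruning,
    full-batch Adam training with gated early stopping, leave-one-subject-out
    and subject-dependent cross-validation, Wilson-score chance thresholds,
    occlusion-based channel importance, and a synthetic hemodynamic-response
    data generator so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
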