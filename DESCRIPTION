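Package: cacharge
Title: Conformation-Adaptive Atomic Charges for a Multi-Spin-State Heme
    Model
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts per-atom ESP-style partial charges of a simplified
    heme-dioxygen binding model in three spin states (singlet, triplet,
    quintuplet) directly from molecular geometry.  Conformations are
    encoded either with atom-centered symmetry functions (one radial term
    per element and one angular term per element pair, under a smooth
    cosine cutoff) or with eleven chemically chosen internal coordinates,
    and an independent random-forest regressor is trained for every
    (atom, spin state) pair.  The ensemble mean is the predicted charge
    and the spread of the individual tree predictions is its uncertainty.
    Includes multi-frame XYZ and charge-table readers and writers, a
    synthetic conformation and charge generator that emulates the
    spin-dependent charge statistics of the heme-O2 system so the whole
    pipeline can be trained and tested end to end, evaluation utilities
    (MAE, RMSE, error standard deviation, Pearson correlation,
    spin-difference histograms, descriptor comparisons), and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
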