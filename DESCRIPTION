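Package: pepccs
Title: Peptide Collisional Cross-Section Prediction for Ion Mobility Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data preparation, training and inference of peptide collisional
    cross-section (CCS) values measured by trapped ion mobility spectrometry.
    Reads MaxQuant- and PEAKS-style identification tables, converts reduced
    ion mobilities to CCS via the Mason-Schamp equation, deduplicates
    (sequence, charge) features with multimodality detection, aligns datasets
    by a linear CCS shift, fits a per-charge square-root baseline in m/z and
    trains a bidirectional gated recurrent unit (GRU) network on the residual
    CCS contribution of the peptide sequence. Also computes CCS-derived
    features for percolator PIN files to rescore peptide-spectrum matches,
    and ships a seedable synthetic-data generator so the full workflow can be
    exercised without external data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: C++17
Config/testthat/edition: 3
RoxygenNote: 7.3.3
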