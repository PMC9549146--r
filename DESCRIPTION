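Package: ieegcontrasts
Title: Uni- and Multivariate Detection of Task-Condition Contrasts in
    Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects brain structures with significant contrasts between two
    task conditions in sparse intracranial EEG (stereo-EEG) recordings, using
    three complementary methods operating on single-trial gamma-band power
    traces: non-parametric cluster-level permutation tests, per-contact
    machine-learning classification scored by the normalized Matthews
    correlation coefficient, and a radius-based searchlight multivariate
    pattern analysis over 3D electrode coordinates. Includes the full spectral
    preprocessing chain (FIR notch filtering, common-average referencing,
    epoching, resampling, Morlet time-frequency decomposition, baseline
    correction, gamma-band averaging), anatomical bookkeeping for depth
    electrode contacts, structure-level aggregation with pairwise Jaccard
    agreement between methods, and a synthetic-cohort simulator with
    controlled condition effects for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
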