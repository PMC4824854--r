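Package: calpainqsar
Title: Quantitative Structure-Activity Models of Calpain Cleavage Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the substrate specificity of the conventional
    calpains (calpain-1 and calpain-2) from oligopeptide digestion data.
    Cleavage-site windows (P10-P10') are featurized with per-position amino-acid
    descriptor scales (AAindex and user-supplied tables); a Bayes binary-QSAR
    classifier predicts cleavability and a partial-least-squares model predicts
    catalytic efficiency (kcat/Km) with backward feature elimination under
    leave-one-out criteria; kcat/Km is estimated from multiplexed isobaric-label
    intensity data by Lineweaver-Burk regression; position-specific frequency
    profiles, proportion tests and decoy-database construction round out the
    specificity analyses. A seeded synthetic-data generator emulates the peptide
    library so everything is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vctrs
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
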