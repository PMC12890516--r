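Package: myorelax
Title: Myosin Relaxed-State Kinetics and Single-Fiber Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies myosin disordered-relaxed (DRX) and super-relaxed
    (SRX) states from Mant-ATP chase fluorescence decays by double-exponential
    fitting, scores theoretical sarcomeric ATP consumption, and implements a
    single-fiber proteomics workflow: MYH-based fiber typing, total-abundance
    normalization, missingness filtering, mixed KNN/MinProb imputation,
    differential abundance with FDR and fold-change gates, treatment
    restoration-set analysis, hypergeometric enrichment and PCA summaries.
    Ships seeded synthetic-data generators for decay cohorts and abundance
    matrices so every stage is testable without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
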