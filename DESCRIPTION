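Package: tbpsnp
Title: Regulatory SNP Effects on TATA-Binding Protein Affinity in Proximal Promoters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores single-nucleotide polymorphisms (SNPs) in 70-bp proximal
    promoters for their effect on the binding affinity of the TATA-binding
    protein (TBP). Implements a sequence-based estimator of the TBP-DNA
    equilibrium dissociation constant (K_D) calibrated against in vitro
    EMSA measurements, Fisher Z-score significance calls for allele pairs,
    exact binomial selection-pressure statistics over marker count tables,
    prediction-versus-experiment validation (unit conversions, Pearson,
    Spearman, Kendall and Goodman-Kruskal correlations), saturation-kinetics
    K_D fitting, and seeded synthetic-data generators for promoters with
    planted TATA elements, marker count tables and binding kinetics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    MASS,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
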