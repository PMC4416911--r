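Package: altipop
Title: Amplicon Variant Calling, Population Genetics and Demographic
    Inference for Altitudinal Plant Population Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-population amplicon resequencing studies along
    elevation gradients: polymorphism calling from read pileups under an
    explicit binomial sequencing-error model with read-backed phasing;
    per-gene diversity, neutrality, linkage and divergence statistics
    (pi, Watterson's theta, Tajima's D, haplotype diversity, ZZ, the
    McDonald-Kreitman test and the DoS index); Hudson F_ST and Jost D_est
    differentiation with altitude-class contrasts; Mantel isolation-by-distance,
    ancestry-asymmetry randomization and Evanno delta-K utilities; Approximate
    Bayesian Computation over four single-population demographic models with a
    built-in coalescent simulator; and structured SNP-climate association with
    permutation inference.  Synthetic-data generators emulate the full study
    design so every stage can be exercised end-to-end without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
LinkingTo: Rcpp
Config/testthat/edition: 3
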