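Package: amaci
Title: Multi-Country Maternal-Effects Animal-Model BLUP for Beef Cattle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pedigree-based BLUP for international beef-cattle weaning-weight
    evaluations under the AMACI model (Animal Model accounting for
    Across-Country Interaction), in which each country is a correlated trait
    with direct and maternal additive-genetic effects. Provides pedigree
    validation and sparse construction of the inverse numerator relationship
    matrix with inbreeding, assembly and preconditioned conjugate-gradient
    solution of the mixed-model equations with a Kronecker trait-by-pedigree
    genetic covariance, scenario masking of direct-maternal genetic
    correlation blocks, unweighted bending of non-positive-definite
    correlation matrices, exact prediction-error-variance reliabilities at
    desk scale, LR-method validation statistics, cohort-wise re-ranking
    reports, and a synthetic multi-country data generator for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, Matrix, stats, utils, yaml
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
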