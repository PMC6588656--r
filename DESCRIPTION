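Package: crosspred
Title: Genomic Prediction and Training-Set Design for Multi-Parent Wheat Breeding Populations
Version: 0.1.0
Authors@R:
    person("crosspred", "developers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates multi-parent wheat breeding populations (founders,
    bi- and tri-parental crosses, F2:4 bulk lines, multi-environment yield
    trials with separable AR1xAR1 spatial noise) and analyses them with the
    standard two-stage genomic prediction workflow: per-trial spatial
    adjustment by restricted maximum likelihood, best linear unbiased
    estimates (BLUEs) of line means across trials, a VanRaden genomic
    relationship matrix, GBLUP variance components by AI-REML with EM
    fallback, Piepho-Mohring heritability on a line-mean basis, and a suite
    of cross-validation designs for studying training-set size and
    relatedness (tenfold by cross or by line, leave-one-cross-out,
    training-set masking, crosses-by-lines grids, and relatedness-stratified
    designs with partial inclusion of the validation cross).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    withr,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
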