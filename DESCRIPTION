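Package: omixblup
Title: Cosine-Kernel Multi-Omics BLUP for Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction with kernel relationship matrices that blend
    genomic and transcriptomic information. Implements VanRaden's genomic
    relationship matrix and Cosine-kernel relationship matrices built from SNP
    dosages or gene-expression profiles, and five prediction models around
    them: GBLUP, TBLUP, MBLUP (a convex blend of the genomic and
    transcriptomic kernels), and two single-step hybrids (mssBLUP and
    wmssBLUP) that embed the expression kernel of a small transcribed subset
    into the genome-wide relationship matrix so untranscribed animals borrow
    transcriptomic information through genomic relationships. Includes
    marker- and gene-level quality control, REML variance-component
    estimation with heritability, leave-one-out and replicated k-fold
    cross-validation, blending-parameter grid searches, a
    transcribed-proportion experiment driver, and a synthetic-population
    simulator emulating a large genotyped herd with a small transcribed
    subset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
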