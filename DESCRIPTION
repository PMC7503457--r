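Package: lncperturb
Title: Identification of lncRNA-Perturbated miRNA-mRNA Triplets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies lncRNA/miRNA/mRNA trios in which the negative
    miRNA-mRNA correlation is rewired between low- and high-lncRNA sample
    strata. Provides a hypergeometric shared-miRNA candidate screen with FDR
    control, a conditional-correlation rewiring score based on the Fisher
    z-transformation with permutation p-values, Cox proportional-hazards
    triplet risk scores with log-rank testing, conservation and
    copy-number/mutation annotation layers, and a synthetic-cohort generator
    with planted triplets for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    survival,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
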