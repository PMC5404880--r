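Package: chromPersist
Title: Consensus Binding Sites and Enhancer Persistence Classification
    from Chromatin Profiling Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives condition-specific transcription-factor binding sites
    from replicate ChIP-seq peak calls by treatment-replicate consensus and
    control subtraction, builds normalized accessibility and histone-mark
    signal matrices around site centers (with ATAC-seq Tn5 offset
    correction and fragment-length read extension), and classifies bound
    sites into factor-dependent (Type 1) and factor-independent (Type 2)
    enhancer classes by the persistence of chromatin accessibility across
    an inducer-withdrawal time course.  Includes positional annotation
    (nearest-TSS distance classes, co-factor peak proximity), enhancer
    mark categories, chi-square accessibility-change testing, PCA of
    sample accessibility, an expression-signature filter, and a
    ground-truthed synthetic data generator so the whole pipeline is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
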