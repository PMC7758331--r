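Package: delbin
Title: Deletion-Bin Dosage Karyotyping and Physical Mapping for Wheat
    Cytogenetic Stocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for read-depth karyotyping of aneuploid and deletion
    stocks of hexaploid wheat from binned genotyping-by-sequencing (GBS)
    read counts, and for deletion-bin physical mapping of a binary
    phenotype. Implements two-step normalization of per-bin counts
    against a euploid reference, log2-ratio dosage-state calling,
    segmentation and karyotype-event classification (nullisomy,
    tetrasomy, ditelosomy, terminal deletions, arm additions),
    fraction-length (FL) breakpoint arithmetic, interval logic that
    intersects deletion calls with seed-viability phenotypes under a
    homoeologous dosage-compensation rule, spike-fertility statistics
    (seed set, potential spikelet productivity, one-way ANOVA with
    Fisher's protected LSD flags), and a count-data simulator that
    generates the full cytogenetic panel with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
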