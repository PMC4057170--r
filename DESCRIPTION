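Package: mbdscape
Title: Genome-Wide Analysis of Methyl-CpG Binding Protein Sites
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of genome-wide binding of a methyl-CpG
    binding domain protein (MBD2-like) from ChIP-seq peaks, base-resolution
    bisulfite methylation calls, and chromatin-mark tag tracks. Provides
    hierarchical annotation of binding sites against gene and CpG-island
    models with matched random nulls, interval methylation and methyl-CpG
    density computation, enrichment-versus-density rank correlation,
    k-means clustering of multi-mark tag-density profiles with
    mirrored-cluster merging, expression-based gene stratification, and
    tumour-versus-normal cohort methylation comparison. A seeded synthetic
    data generator plants all of these structures in a toy genome so every
    stage can be tested against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
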