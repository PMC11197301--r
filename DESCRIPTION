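Package: grapediverge
Title: Comparative and Population Genomics of Grape Divergence and Sex
    Determination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative-genomics and population-genomics analyses
    used in wild grape (Vitis) genome studies: Nei-Gojobori (1986) Ka/Ks
    estimation with Jukes-Cantor correction, Gaussian-mixture fitting of Ks
    distributions and molecular-clock divergence dating anchored on the core
    eudicot-common hexaploidy, collinear block chaining and paralog
    classification, windowed species-specific segment and presence/absence
    variation (PAV) gene calling, theta-pi/FST selective-sweep scanning with
    sex-determination-region overlap, region-restricted SNP phylogenies,
    ortholog-anchored interval lift-over with haplotype gene-content
    comparison, and node-removal network robustness. A synthetic-data module
    generates every input class with known ground truth so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    igraph,
    IRanges,
    jsonlite,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
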