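Package: divsig
Title: Signatures of Selection in Divergently Selected Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and validation of signatures of selection in divergent
    selection experiments genotyped on SNP arrays. Implements consensus scanning
    of runs of homozygosity, windowed Weir-Cockerham FST with a drift-versus-
    selection minor-allele-frequency rule, varLD contrasts of linkage-
    disequilibrium structure via eigendecomposition of windowed r2 matrices,
    cross-generation validation of putative signatures, and prioritization of
    functional mutations (UTR, missense, frameshift, splicing) fixed divergently
    between lines. Ships a Wright-Fisher forward simulator of a divergent
    selection experiment (founder-mosaic haplotypes, recombination,
    multiplicative selection) for end-to-end exercise of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
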