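Package: strpopgen
Title: Population Genetics of Short Tandem Repeats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population-scale analysis of short tandem repeat
    (STR) genotypes called from sequencing data: allele-frequency
    diversity statistics (PIC, Shannon's index, heterozygote/homozygote
    ratios, expansion scores), Rst differentiation scans with candidate
    differentiated region merging, stepwise-mutation-model genetic
    distances with neighbour-joining trees, indicator-matrix PCA for
    multiallelic markers, environmental association scans with
    principal-component covariates, genomic feature enrichment and
    hotspot detection, and STR-versus-SNP signal comparison. Includes a
    forward-time stepwise-mutation-model simulator of diverging
    populations for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    vcfR,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
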