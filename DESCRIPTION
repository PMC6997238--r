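Package: diplosim
Title: Simulation of Diploid Personal Genomes from Variant Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans, samples and generates diploid human-genome sequences whose
    variants are drawn from known- and common-variant databases (allele-frequency
    weighted, population aware), generated de novo under empirical mutation laws
    (transition/transversion ratio, indel rate, power-law indel lengths,
    coding/non-coding asymmetry), and spiked with structural and pathogenic
    variants taken from reference databases. The three-stage pipeline (planner,
    simulator, generator) emits a phased single-sample VCF, one FASTA file per
    haplotype, and block-wise coordinate maps between reference and haplotype
    coordinates. A synthetic fixture generator builds complete miniature input
    datasets (reference, coding BED and all four variant databases) so every
    stage can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
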