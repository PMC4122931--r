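Package: endoerode
Title: Genome Erosion, Rearrangement and Gap-Closure Analysis for
    Endosymbiont Genomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for the computational procedures used to
    finish and interpret a highly mobile-element-rich facultative
    endosymbiont genome: repeat-masked gap-closure primer design over
    N-gapped scaffolds (de novo k-mer repeat masking, nearest-neighbor
    melting temperatures, gap-spanning primer pair selection), per-strain
    gene-state matrices (intact/pseudogene/absent) from a 30%-of-self
    local alignment score rule with Dollo assignment of inactivation
    events to branches of a fixed species topology, COG functional
    category frequency profiles and degradation divergence from a
    free-living mean, syntenic-cluster and breakpoint-distance analysis
    of signed single-copy gene orders, and a discordant mate-pair screen
    for intrapopulation rearrangements. Every stage is exercisable on
    synthetic genomes and simulated mate-pair libraries with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
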