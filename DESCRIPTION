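Package: fmphase
Title: Resolving the Fibromelanosis Duplication-Inversion Locus from Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to resolve the complex duplication-inversion rearrangement at
    the chicken fibromelanosis (Fm) locus from long-read alignments against an
    un-rearranged reference: coverage-based duplication breakpoint detection,
    junction-spanning read classification by an orientation grammar, read-backed
    haplotype extension across the duplicated regions, and arrangement-scenario
    inference from anchored haplotype contexts. Includes a synthetic-data module
    that builds rearranged diploid genomes, planted heterozygous sites, simulated
    long- and short-read alignments and multi-population haplotype panels, and a
    windowed population-genetic sweep scan (pi, Watterson's theta, Tajima's D,
    Fu and Li's D*, Hudson's FST, Dxy, iHS, XP-EHH) with callability and repeat
    filtering and empirical-quantile outlier calling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    GenomicRanges,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
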