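Package: sweepscan
Title: Genome-Wide Selective Sweep Scans from Two-Population Variant Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects selective sweeps from two-population diploid variant
    data using four windowed statistics: Weir-Cockerham Fst, pooled
    heterozygosity (Hp), the nucleotide-diversity ratio between reference
    and target populations, and the cross-population extended haplotype
    homozygosity score (XP-EHH). Statistics are computed in sliding
    windows, Z-transformed genome-wide, and converted to one-sided normal
    P-values; windows that are outliers (P < 0.005) for two or more
    statistics are merged into consensus candidate regions and annotated
    with overlapping genes. Includes GATK-style site hard filters,
    MAF/missingness filters, LD pruning, genotype PCA with Patterson
    normalization, and a two-population Wright-Fisher simulator that
    plants a selective sweep and emits phased VCF fixtures with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
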