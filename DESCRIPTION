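Package: graftrans
Title: Detection of Graft-Mobile mRNAs and Estimation of Transmission Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects mRNAs that move across the graft junction between two
    genetically distinct graft partners (scion and rootstock) from bulk
    RNA-Seq, using diagnostic SNPs derived from genomic sequencing of the two
    partners. Provides pileup-based homozygous genotype calling, diagnostic
    SNP derivation, allele-specific classification of receptor-tissue reads,
    rule-based calling of graft-transmitting genes, window-based RPM-normalized
    per-SNP and per-gene mRNA transmission-rate estimation, and RPKM gene
    expression summaries. A self-contained synthetic-data generator emulates
    grafted-plant sequencing experiments (two homozygous genotypes, planted
    SNPs, directional transcript mixing, sequencing error, PCR duplication)
    with machine-readable ground truth, and a built-in ungapped test aligner
    lets the whole pipeline run without any external mapper.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
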