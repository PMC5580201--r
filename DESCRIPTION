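Package: snpsignal
Title: Genome-Wide SNP Signal-Intensity Scan for Two-Group Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for differentiating two groups of samples from the raw
    fluorescence intensities of a SNP genotyping array, without using the
    called genotypes. Per-SNP allele intensities are summed (T = A + B) and
    normalized as log2(T/M) against the across-sample median M; genes with at
    least 15 array SNPs are scanned with a two-sided F-test for equality of
    variance and a Welch t-test for equality of means over per-gene vectors of
    normalized values; the Benjamini-Hochberg step-up rule controls the false
    discovery rate; principal components analysis confirms sample
    differentiation. Includes a seeded synthetic-data generator with planted
    per-gene mean-shift and variance-inflation effects for power and FDR
    evaluation, plus region-level utilities: flanking-SNP and arbitrary-region
    tests, a copy-number-variant declaration filter, interval overlap, pathway
    coverage arithmetic, and haplotype group-consistency checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    GenomicRanges,
    IRanges,
    S4Vectors,
    withr
Config/testthat/edition: 3
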