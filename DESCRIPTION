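Package: ovisweep
Title: Within-Population Selection-Signature Scans from SNP-Array Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects footprints of recent selection in a single livestock
    population from medium-density SNP-array data. Implements genotype
    quality control, genetic-diversity and identity-by-state statistics,
    genomic inbreeding coefficients (F_ROH, F_HOM), sliding-window
    runs-of-homozygosity (ROH) detection with ROH-island sweep calling, and
    the integrated haplotype score (iHS) scan from phased haplotypes with
    extreme-SNP and 500-kb region calling. A haplotype simulator with
    planted selective sweeps and autozygous tracts provides
    parameter-recovery validation without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
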