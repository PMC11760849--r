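Package: rohload
Title: Mutational Load and Runs-of-Homozygosity Analysis for Paired Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantifying mutational load and inbreeding
    from multi-sample SNP data in two related populations. Implements variant
    quality-control filtering (hard filters, depth-percentile and missingness
    filters), coding-consequence annotation against gene models with Grantham
    distance scoring of amino-acid changes, ancestral-allele polarization by
    outgroup majority rule, PLINK-style detection of runs of homozygosity with
    F_ROH inbreeding coefficients, per-individual load statistics (derived-allele
    counts, homozygous dosage, occurrence ratios inside and outside ROH),
    windowed nucleotide diversity and linkage-disequilibrium decay, and a
    synthetic-data generator that emulates two populations with shared ancestry,
    planted autozygous tracts and class-specific derived-allele-frequency
    structure, with machine-readable truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    rtracklayer,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
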